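#' Read a pedigree script
#'
#' CSV with columns `id`, `type`, `parent1`, `parent2`. `type` is one of
#' `founder:<species>` (e.g. `founder:kousa`), `cross` (parent1 x parent2),
#' `self` (parent1), `op` (open pollination: parent1 = mother, parent2
#' optionally the assumed pollen species label), `clone` or `apomict`
#' (parent1).
#'
#' @param path CSV path.
#' @return validated data.frame in file order.
#' @export
readPedigree <- function(path) {
    p <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "type", "parent1", "parent2")
    if (!all(need %in% colnames(p)))
        stop("pedigree must contain columns ", paste(need, collapse = ", "))
    .validatePedigree(p)
    p
}

.pedType <- function(type) sub(":.*$", "", type)

# species label of a founder node; an optional subspecies suffix
# (founder:kousa:chinensis) is dropped here and consumed by the simulator
.founderSpecies <- function(type) {
    sp <- sub(":.*$", "", sub("^founder:?", "", type))
    ifelse(sp == "", NA_character_, sp)
}

.founderSubspecies <- function(type) {
    rest <- sub("^founder:?", "", type)
    parts <- strsplit(rest, ":", fixed = TRUE)
    vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
           character(1))
}

.validatePedigree <- function(ped, known = character(0)) {
    if (anyDuplicated(ped$id)) stop("duplicate pedigree ids")
    base <- .pedType(ped$type)
    bad <- setdiff(unique(base),
                   c("founder", "cross", "self", "op", "clone", "apomict"))
    if (length(bad)) stop("invalid pedigree type(s): ", paste(bad, collapse = ", "))
    isF <- base == "founder"
    if (any(isF & is.na(.founderSpecies(ped$type))))
        stop("founder nodes must carry a species label (founder:<species>)")
    # parents must be declared earlier (topological file order) and acyclic
    seen <- known
    for (k in seq_len(nrow(ped))) {
        tp <- base[k]
        req <- switch(tp, founder = character(0),
                      cross = c(ped$parent1[k], ped$parent2[k]),
                      op = ped$parent1[k],
                      c(ped$parent1[k]))
        req <- req[!is.na(req) & req != ""]
        miss <- setdiff(req, seen)
        if (length(miss))
            stop("node '", ped$id[k], "' references undeclared parent(s): ",
                 paste(miss, collapse = ", "),
                 " (pedigree must be declared in topological order; cycles are invalid)")
        seen <- c(seen, ped$id[k])
    }
    invisible(TRUE)
}

#' Pedigree-expected species composition
#'
#' Propagates expected species percentages through a pedigree: founders are
#' 100% their own species; a cross (or self) takes the arithmetic mean of
#' its parents' vectors (a self equals its single parent); an open
#' pollination averages the mother's vector with the pure vector of the
#' assumed pollen species; clones and apomicts copy their parent. The donor
#' fraction therefore halves with each backcross to the recurrent species:
#' F1 = 50/50, BC1 = 75/25, BC2 = 87.5/12.5, BC3 donor = 6.25%.
#'
#' @param pedigree data.frame as from [readPedigree()].
#' @param opSpecies species assumed to pollinate open-pollination events when
#'   a node's `parent2` does not name one (default `"kousa"`, the recurrent
#'   species assumption).
#' @param species optional character vector fixing the species set/order of
#'   the result; inferred from founder labels (plus `opSpecies`) when `NULL`.
#' @return matrix of expected percentages, nodes x species, rows summing
#'   to 100.
#' @export
expectedComposition <- function(pedigree, opSpecies = "kousa", species = NULL) {
    .validatePedigree(pedigree)
    base <- .pedType(pedigree$type)
    fsp <- ifelse(base == "founder", .founderSpecies(pedigree$type),
                  NA_character_)
    opsp <- ifelse(base == "op" & !is.na(pedigree$parent2) & pedigree$parent2 != "",
                   pedigree$parent2, opSpecies)
    if (is.null(species))
        species <- sort(unique(c(fsp[!is.na(fsp)], opsp[base == "op"])))
    pure <- function(sp) {
        if (!sp %in% species)
            stop("species '", sp, "' not in the species set")
        v <- setNames(numeric(length(species)), species)
        v[sp] <- 100
        v
    }
    E <- matrix(NA_real_, nrow(pedigree), length(species),
                dimnames = list(pedigree$id, species))
    for (k in seq_len(nrow(pedigree))) {
        id <- pedigree$id[k]
        E[id, ] <- switch(base[k],
            founder = pure(fsp[k]),
            cross = (E[pedigree$parent1[k], ] + E[pedigree$parent2[k], ]) / 2,
            self = E[pedigree$parent1[k], ],
            op = (E[pedigree$parent1[k], ] + pure(opsp[k])) / 2,
            clone = E[pedigree$parent1[k], ],
            apomict = E[pedigree$parent1[k], ])
    }
    E
}
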