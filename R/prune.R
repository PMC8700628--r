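#' Prune the top-scoring fraction of genes
#'
#' Sorts genes by pruning score in decreasing order (ties broken by gene
#' identifier, lexicographic ascending), removes the first
#' `floor(fraction * n)` genes — the strongest class discriminators — and
#' returns the survivors in their original order. In the two-stage workflow
#' the scores come from [classDirectionScores()] on the normal-tissue model,
#' so the removed genes are the gut-segment-confounded discriminators.
#'
#' @param scores named non-negative scores, one per gene.
#' @param fraction fraction of genes to remove, in \[0, 1).
#' @return the kept gene identifiers, in the original score order.
#' @examples
#' pruneTopFraction(c(g1 = 0.9, g2 = 0.5, g3 = 0.2, g4 = 0.1), 0.5)
#' @export
pruneTopFraction <- function(scores, fraction) {
    if (!length(scores)) stop("`scores` must be non-empty")
    if (is.null(names(scores)) || anyDuplicated(names(scores)))
        stop("`scores` must be named with unique gene identifiers")
    if (fraction < 0 || fraction >= 1)
        stop("`fraction` must lie in [0, 1): pruning everything would ",
             "empty the gene set")
    n_remove <- floor(fraction * length(scores))
    if (n_remove == 0) return(names(scores))
    drop <- order(-scores, names(scores))[seq_len(n_remove)]
    names(scores)[-drop]
}
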