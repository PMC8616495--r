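#' Weighted enrichment score of a gene set in a ranked signature
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: genes are ranked by
#' decreasing z-score; walking down the ranking, hits (gene-set members)
#' advance the sum by `|z|^exponent` (normalized over hits) and misses
#' retreat it by `1/(N - Nh)`. The score is the running sum's maximum
#' deviation from zero, signed: positive when the set concentrates at the
#' top of the ranking, negative at the bottom. Ties in `z` are broken by
#' gene id so the ranking is stable.
#'
#' @param z named numeric vector of z-scores (one signature over the gene
#'   universe).
#' @param gene_set character vector of gene ids; genes outside the universe
#'   are dropped with a warning, an empty intersection is an error.
#' @param exponent weighting exponent on `|z|` (1 = CMap-style weighting,
#'   0 = classic unweighted KS).
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(z, gene_set, exponent = 1) {
  if (is.null(names(z))) stop("'z' must be a named vector")
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, names(z))
  if (length(missing) == length(gene_set))
    stop("gene set has no overlap with the signature's gene universe")
  if (length(missing))
    warning(sprintf("%d gene(s) of the set absent from the universe; dropped",
                    length(missing)))
  gene_set <- setdiff(gene_set, missing)
  ord <- order(-z, names(z), method = "radix")
  zr <- z[ord]
  .es_ranked(abs(zr)^exponent, names(zr) %in% gene_set)
}

# running-sum ES on an already-ranked signature: wr = |z|^exponent in rank
# order, hit = membership indicator in rank order
.es_ranked <- function(wr, hit) {
  n <- length(wr); nh <- sum(hit)
  if (nh == n) return(1)
  wh <- wr * hit
  denom <- sum(wh)
  if (denom == 0) wh[hit] <- 1 / nh else wh <- wh / denom
  run <- cumsum(wh - (!hit) / (n - nh))
  unname(run[which.max(abs(run))])
}

#' Weighted two-sided connectivity score (wtcs)
#'
#' Enrichment of the query's up and down sets in one signature, combined as
#' `(es_up - es_down) / 2` when the two scores have opposite signs and 0
#' otherwise (a query whose up and down sets move the same way carries no
#' directional information).
#'
#' @param query a `query_signature` (list with `up`, `down`) as produced by
#'   [build_query_signature()] or [generate_signature_library()].
#' @param z named z-score vector of one library signature.
#' @param exponent see [enrichment_score()].
#' @return List with `es_up`, `es_down`, `wtcs`, each in `[-1, 1]`.
#' @export
wtcs <- function(query, z, exponent = 1) {
  es_up <- enrichment_score(z, query$up, exponent)
  es_down <- enrichment_score(z, query$down, exponent)
  w <- if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
  list(es_up = es_up, es_down = es_down, wtcs = w)
}

#' Score a query signature against a whole library
#'
#' @param query a `query_signature`.
#' @param library a `signature_library` (or a genes x signatures z matrix).
#' @param exponent see [enrichment_score()].
#' @return Data frame with one row per signature: `signature_id`,
#'   `perturbagen_id`, `class` (when available), `es_up`, `es_down`, `wtcs`.
#' @export
score_library <- function(query, library, exponent = 1) {
  z <- if (inherits(library, "signature_library")) library$z else library
  meta <- if (inherits(library, "signature_library")) library$meta else
    data.frame(signature_id = colnames(z),
               perturbagen_id = colnames(z),
               class = NA_character_)
  genes <- rownames(z)
  up <- intersect(query$up, genes); down <- intersect(query$down, genes)
  if (length(up) == 0 || length(down) == 0)
    stop("query has no overlap with the library's gene universe")
  if (length(up) < length(unique(query$up)) ||
      length(down) < length(unique(query$down)))
    warning("query genes absent from the library universe were dropped")
  res <- lapply(seq_len(ncol(z)), function(s) {
    zs <- z[, s]
    ord <- order(-zs, genes, method = "radix")
    wr <- abs(zs[ord])^exponent
    gn <- genes[ord]
    es_up <- .es_ranked(wr, gn %in% up)
    es_down <- .es_ranked(wr, gn %in% down)
    w <- if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
    data.frame(signature_id = meta$signature_id[s],
               perturbagen_id = meta$perturbagen_id[s],
               class = meta$class[s], es_up = es_up,
               es_down = es_down, wtcs = w)
  })
  do.call(rbind, res)
}

#' Normalize raw connectivity scores and convert to tau percentiles
#'
#' Within each stratum, `ncs` divides each wtcs by the mean of the same-sign
#' wtcs values of that stratum (signed normalization); `tau` is the signed
#' percentile of `|ncs|` against the stratum's own `|ncs|` reference
#' distribution (fraction of the other members strictly below), scaled to
#' `[-100, 100]`. The stratum maximum therefore maps to +-100 exactly and a
#' zero score to 0. Strata with fewer than 20 signatures give
#' unstable percentiles and trigger a warning; a stratum with no same-sign
#' score yields `NA` ncs.
#'
#' @param scores data frame from [score_library()].
#' @param strata optional factor/character vector (one per row) defining
#'   normalization strata; default: one stratum for the whole library.
#' @return `scores` with `ncs` and `tau` columns appended (a
#'   `connectivity_result` data frame).
#' @export
normalize_and_tau <- function(scores, strata = NULL) {
  n <- nrow(scores)
  if (is.null(strata)) strata <- rep("all", n)
  strata <- as.character(strata)
  ncs <- rep(NA_real_, n); tau <- rep(NA_real_, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 20)
      warning(sprintf("stratum '%s' has only %d signatures; percentiles unstable",
                      s, length(idx)))
    w <- scores$wtcs[idx]
    mpos <- mean(w[w > 0]); mneg <- mean(w[w < 0])
    v <- ifelse(w > 0, w / mpos, ifelse(w < 0, -w / mneg, 0))
    # w == 0 maps to 0; sign(ncs) == sign(wtcs)
    ncs[idx] <- v
    av <- abs(v)
    ref <- av[!is.na(av)]
    denom <- max(length(ref) - 1L, 1L)  # stratum max maps to +-100 exactly
    tau[idx] <- sign(v) * 100 * vapply(av, function(x)
      if (is.na(x)) NA_real_ else sum(ref < x) / denom, numeric(1))
  }
  out <- scores
  out$ncs <- ncs
  out$tau <- tau
  stopifnot(all(is.na(out$tau) | abs(out$tau) <= 100))
  class(out) <- c("connectivity_result", "data.frame")
  out
}

#' Summarize connectivity results per perturbagen
#'
#' Median tau over each perturbagen's signatures, ranked in descending
#' order, with a top-k report and the class composition of the top 100
#' (how often each perturbagen class appears among the strongest hits).
#'
#' @param results a [normalize_and_tau()] data frame.
#' @param top_k size of the reported top list.
#' @return A `perturbagen_summary`: `table` (perturbagen_id, median_tau,
#'   n_signatures, class; sorted), `top` (head of the table), and
#'   `class_in_top100` (class counts among the 100 best).
#' @export
summarize_perturbagens <- function(results, top_k = 20) {
  if (nrow(results) == 0) stop("no results to summarize")
  sp <- split(results, results$perturbagen_id)
  tab <- data.frame(
    perturbagen_id = names(sp),
    median_tau = vapply(sp, function(d) median(d$tau), numeric(1)),
    n_signatures = vapply(sp, nrow, integer(1)),
    class = vapply(sp, function(d) as.character(d$class[1]), character(1)))
  tab <- tab[order(-tab$median_tau, tab$perturbagen_id), ]
  rownames(tab) <- NULL
  structure(list(table = tab, top = head(tab, top_k),
                 class_in_top100 = table(head(tab, 100)$class)),
            class = "perturbagen_summary")
}

#' @export
print.perturbagen_summary <- function(x, ...) {
  cat(sprintf("perturbagen_summary: %d perturbagens; top %d:\n",
              nrow(x$table), nrow(x$top)))
  print(x$top, row.names = FALSE)
  invisible(x)
}
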