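#' Generate a synthetic perturbagen signature library
#'
#' Emulates a Connectivity-Map-style library of z-scored gene signatures with
#' planted structure relative to a query template: signatures of the
#' "concordant" class are positively correlated with the template
#' (`z = rho * template + sqrt(1 - rho^2) * noise`), "discordant" signatures
#' negatively, and "null" signatures are independent draws. Each perturbagen
#' contributes `replicates` signatures. A query (top/bottom genes of the
#' template) is returned with the library.
#'
#' @param gene_universe character vector of gene ids (default 1,000 synthetic
#'   landmark-style genes).
#' @param n_perturbagens number of perturbagens (desk-scale stand-in for a
#'   library of thousands).
#' @param class_fractions named fractions for `concordant`, `discordant`,
#'   `null`; must sum to 1. Defaults plant 8% in each informative class:
#'   small enough that a planted perturbagen's |score| percentile within the
#'   library stays extreme (the class median tau is then ~92), large enough
#'   that the concordant class alone (20 perturbagens) can fill a top-20
#'   ranking.
#' @param replicates signatures per perturbagen.
#' @param concordance correlation `rho` of planted classes with the template.
#' @param n_query size of each of the up and down query sets taken from the
#'   template extremes.
#' @param seed RNG seed.
#' @return A `signature_library`: list with `z` (genes x signatures matrix),
#'   `meta` (signature_id, perturbagen_id, class), `template` (named z
#'   vector), and `query` (list with `up`, `down`).
#' @export
generate_signature_library <- function(gene_universe = sprintf("G%06d", 1:1000),
                                       n_perturbagens = 250,
                                       class_fractions = c(concordant = 0.08,
                                                           discordant = 0.08,
                                                           null = 0.84),
                                       replicates = 2, concordance = 0.7,
                                       n_query = 50, seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("'class_fractions' must sum to 1")
  n_g <- length(gene_universe)
  if (2 * n_query > n_g)
    stop("gene universe smaller than the requested up/down set sizes")
  counts <- round(class_fractions * n_perturbagens)
  counts[1] <- n_perturbagens - sum(counts[-1])
  classes <- rep(names(class_fractions), counts)
  with_seed(seed, {
    template <- stats::setNames(rnorm(n_g), gene_universe)
    n_sig <- n_perturbagens * replicates
    z <- matrix(NA_real_, n_g, n_sig)
    meta <- data.frame(
      signature_id = sprintf("sig_%04d", seq_len(n_sig)),
      perturbagen_id = rep(sprintf("pert_%03d", seq_len(n_perturbagens)),
                           each = replicates),
      class = rep(classes, each = replicates))
    for (s in seq_len(n_sig)) {
      eps <- rnorm(n_g)
      z[, s] <- switch(meta$class[s],
        concordant = concordance * template + sqrt(1 - concordance^2) * eps,
        discordant = -concordance * template + sqrt(1 - concordance^2) * eps,
        null = eps)
    }
    dimnames(z) <- list(gene_universe, meta$signature_id)
    ord <- order(template, decreasing = TRUE)
    query <- list(up = gene_universe[head(ord, n_query)],
                  down = gene_universe[rev(ord)[seq_len(n_query)]])
    structure(list(z = z, meta = meta, template = template, query = query,
                   concordance = concordance, seed = seed),
              class = "signature_library")
  })
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf(
    "signature_library: %d genes x %d signatures (%d perturbagens; %s)\n",
    nrow(x$z), ncol(x$z), length(unique(x$meta$perturbagen_id)),
    paste(sprintf("%s=%d", names(table(x$meta$class)), table(x$meta$class)),
          collapse = ", ")))
  invisible(x)
}
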