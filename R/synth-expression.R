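#' Generate a synthetic expression panel coupled to aggregation parameters
#'
#' Emulates a log-expression matrix (genes x cell lines) in which a small
#' planted set of genes is linearly coupled to each aggregation parameter:
#' `expr = baseline + beta * standardize(parameter) + noise`, with
#' `beta = +-effect_size` (sign alternating) and `noise ~ N(0, noise_sd)`.
#' Non-planted genes are independent of all parameters. The planted
#' metadata (gene, target parameter, coefficient) is returned for recovery
#' scoring.
#'
#' @param params_per_line data frame with one row per cell line and columns
#'   `area_2h`, `auc`, `circularity` (any subset of numeric columns is
#'   accepted; each column gets its own planted genes). Row names, if set,
#'   become line ids.
#' @param n_genes total number of genes.
#' @param n_planted_per_parameter planted genes per parameter column.
#' @param effect_size absolute coupling coefficient (log-expression units per
#'   SD of the parameter).
#' @param noise_sd residual noise sd.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param seed RNG seed.
#' @return An `expression_panel`: list with `matrix` (genes x lines),
#'   `gene_ids`, `line_ids`, `planted` (data frame: gene, parameter, beta)
#'   and `params` (the input parameter table).
#' @export
generate_expression_panel <- function(params_per_line, n_genes = 20000,
                                      n_planted_per_parameter = 100,
                                      effect_size = 2, noise_sd = 1,
                                      baseline_mean = 6, baseline_sd = 1.5,
                                      seed = 1) {
  params_per_line <- as.data.frame(params_per_line)
  n_lines <- nrow(params_per_line)
  if (n_lines < 3) stop("need at least 3 cell lines")
  num <- vapply(params_per_line, is.numeric, logical(1))
  params <- params_per_line[num]
  n_par <- ncol(params)
  if (n_par < 1) stop("no numeric parameter columns")
  for (nm in names(params))
    if (sd(params[[nm]]) == 0)
      stop("parameter column '", nm, "' has zero variance")
  if (n_planted_per_parameter * n_par > n_genes)
    stop("more planted genes than genes available")
  line_ids <- rownames(params_per_line)
  if (is.null(line_ids) || all(line_ids == as.character(seq_len(n_lines))))
    line_ids <- sprintf("line_%02d", seq_len(n_lines))
  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  with_seed(seed, {
    base <- rnorm(n_genes, baseline_mean, baseline_sd)
    mat <- matrix(rnorm(n_genes * n_lines, 0, noise_sd), n_genes, n_lines) + base
    planted_idx <- sample.int(n_genes, n_planted_per_parameter * n_par)
    planted <- data.frame(gene = gene_ids[planted_idx],
                          parameter = rep(names(params),
                                          each = n_planted_per_parameter),
                          beta = effect_size *
                            rep_len(c(1, -1), n_planted_per_parameter * n_par))
    for (j in seq_len(n_par)) {
      zpar <- as.numeric(scale(params[[j]]))
      rows <- planted_idx[seq_len(n_planted_per_parameter) +
                            (j - 1L) * n_planted_per_parameter]
      beta <- planted$beta[(j - 1L) * n_planted_per_parameter +
                             seq_len(n_planted_per_parameter)]
      mat[rows, ] <- mat[rows, ] + outer(beta, zpar)
    }
    dimnames(mat) <- list(gene_ids, line_ids)
    structure(list(matrix = mat, gene_ids = gene_ids, line_ids = line_ids,
                   planted = planted,
                   params = stats::setNames(as.data.frame(params,
                                                          row.names = line_ids),
                                            names(params)),
                   effect_size = effect_size, noise_sd = noise_sd,
                   seed = seed),
              class = "expression_panel")
  })
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d genes x %d lines, %d planted gene(s)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$planted)))
  invisible(x)
}

#' Generate synthetic aggregation parameters for a panel of cell lines
#'
#' Draws per-line kinetics models (plateau, rate) and derives the three
#' aggregation parameters analytically, mimicking the between-line
#' heterogeneity of a cell-line panel: `area_2h` and `auc` are driven by the
#' same underlying kinetics (hence correlated), circularity is independent.
#'
#' @param n_lines number of cell lines.
#' @param window_h AUC window (hours).
#' @param seed RNG seed.
#' @return Data frame with rownames `line_01..` and columns `area_2h`,
#'   `auc`, `circularity`.
#' @export
generate_line_parameters <- function(n_lines = 25, window_h = 24, seed = 1) {
  with_seed(seed, {
    a_inf <- runif(n_lines, 0.35, 0.95)
    k <- runif(n_lines, 0.3, 2)
    area2h <- auc <- numeric(n_lines)
    for (i in seq_len(n_lines)) {
      m <- kinetics_model(a_inf[i], k[i])
      area2h[i] <- kinetics_area(m, 2)
      auc[i] <- kinetics_auc(m, window_h)
    }
    data.frame(area_2h = area2h, auc = auc,
               circularity = runif(n_lines, 0.3, 0.9),
               row.names = sprintf("line_%02d", seq_len(n_lines)))
  })
}
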