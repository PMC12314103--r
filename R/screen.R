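# All permutations of 1..n as an n! x n matrix (n <= 7 guarded by caller).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with p-value
#'
#' Ranks with mid-rank ties; `rho` is the Pearson correlation of the
#' ranks. The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` by default, or a permutation test:
#' exhaustive over all `n!` orderings when `n <= 7`, Monte-Carlo
#' otherwise. Pairs with missing values are dropped listwise.
#'
#' @param x,y Paired numeric vectors.
#' @param method `"t_approx"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo resamples when exhaustive enumeration is
#'   infeasible.
#' @return List with `rho`, `p`, `n` (complete pairs) and `method`.
#'   Constant input yields `rho = NA` with a warning.
#' @export
spearman_rho_p <- function(x, y, method = c("t_approx", "permutation"),
                           n_perm = 10000) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = method))
  }
  rho <- stats::cor(rx, ry)
  if (method == "t_approx") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
  } else {
    obs <- abs(rho) - 1e-12
    if (factorial(n) <= 5040) {
      perms <- all_perms(n)
      rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
      p <- mean(abs(rhos) >= obs)
    } else {
      hits <- sum(vapply(seq_len(n_perm), function(i)
        abs(stats::cor(rx, sample(ry))) >= obs, logical(1)))
      p <- (hits + 1) / (n_perm + 1)
    }
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Screen every parameter against every rubric category
#'
#' Spearman rank correlation of each parameter cell (metric x hand x
#' phase) of the cohort table against each of the nine category mean
#' scores, across surgeons. No multiple-testing correction is applied by
#' default; an optional Benjamini-Hochberg adjustment is available.
#'
#' @param cohort A `cohort_table` from [build_cohort_table()].
#' @param scores A `surgeon_scores` tibble from [average_scores()].
#' @param alpha Significance level (default 0.05).
#' @param method p-value method, see [spearman_rho_p()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble with one row per (metric, hand, phase, category):
#'   `rho`, `p`, `n`, `significant`.
#' @export
screen_parameters <- function(cohort, scores, alpha = 0.05,
                              method = "t_approx", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  shared <- intersect(unique(cohort$surgeon), scores$surgeon)
  if (length(shared) < 4L)
    stop("fewer than 4 surgeons shared between cohort and scores",
         call. = FALSE)
  cats <- rubric_categories()
  cells <- dplyr::distinct(cohort, .data$metric, .data$hand, .data$phase)
  rows <- purrr::pmap(cells, function(metric, hand, phase) {
    vals <- cohort_matrix(cohort,
                          tibble::tibble(metric = metric, hand = hand,
                                         phase = phase))[shared, 1L]
    purrr::map_dfr(cats, function(cat) {
      sc <- setNames(scores[[cat]], scores$surgeon)[shared]
      res <- tryCatch(
        suppressWarnings(spearman_rho_p(vals, sc, method = method)),
        error = function(e) list(rho = NA_real_, p = NA_real_,
                                 n = sum(is.finite(vals) & is.finite(sc))))
      tibble::tibble(metric = metric, hand = hand, phase = phase,
                     category = cat, rho = res$rho, p = res$p, n = res$n)
    })
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Select discriminant-model features from a screening table
#'
#' Implements the feature-inclusion rule: within each parameter family
#' (vessel-derived: CV-VA, Max-dVA, No. of TDE; motion-derived: PD and
#' NJI per hand), each parameter with at least one significant category
#' contributes its best phase cell, i.e. the phase whose cell is
#' significantly correlated with the largest number of technical
#' categories. Ties are broken by the smaller median p over the nine
#' categories, then by phase order A, B, C, D, All. Model 1 takes the
#' vessel family, Model 2 the motion family, and Model 3 their union.
#'
#' @param screen Screening tibble from [screen_parameters()] (or from
#'   [read_screen_pvalues()]); needs columns `metric`, `hand`, `phase`,
#'   `category`, `p`, `significant`.
#' @return List with elements `model1`, `model2`, `model3`, each a tibble
#'   of selected cells (`metric`, `hand`, `phase`, `n_significant`,
#'   `median_p`). Empty tibbles (with a warning) when a family has no
#'   significant cell.
#' @export
select_model_features <- function(screen) {
  cells <- dplyr::summarise(
    dplyr::group_by(screen, .data$metric, .data$hand, .data$phase),
    n_significant = sum(.data$significant, na.rm = TRUE),
    median_p = median(.data$p, na.rm = TRUE), .groups = "drop")
  phase_rank <- match(cells$phase, phase_levels(include_all = TRUE))
  cells <- cells[order(cells$metric, cells$hand, -cells$n_significant,
                       cells$median_p, phase_rank), , drop = FALSE]
  best <- dplyr::ungroup(dplyr::slice_head(
    dplyr::group_by(cells, .data$metric, .data$hand), n = 1L))
  best <- best[best$n_significant > 0L, , drop = FALSE]
  vessel <- best[best$metric %in% c("cv_va", "max_dva", "n_tde"), ]
  motion <- best[best$metric %in% c("pd", "nji"), ]
  if (nrow(vessel) == 0L)
    warning("no significant vessel-derived cell: Model 1 is empty")
  if (nrow(motion) == 0L)
    warning("no significant motion-derived cell: Model 2 is empty")
  order_cells <- function(df)
    df[order(df$metric, df$hand, df$phase),
       c("metric", "hand", "phase", "n_significant", "median_p")]
  list(model1 = order_cells(vessel), model2 = order_cells(motion),
       model3 = order_cells(dplyr::bind_rows(vessel, motion)))
}

#' Read a published screening p-value table
#'
#' Parses a CSV rendering of a printed Spearman screening table: one row
#' per (parameter, phase), one column per category code (IH, RT, Ef, SH,
#' ST, QK, FP, OF, OP), with entries as printed, e.g. `0.03*`,
#' `<0.01**`, `0.05`. Stars mark cells the source reports as significant
#' at p < 0.05 (printed values are rounded to two decimals, so an
#' unstarred `0.05` is not significant while a starred one is);
#' `<0.01` is encoded numerically as 0.005.
#'
#' @param path CSV path (the bundled table lives at
#'   `system.file("extdata", "reference_screen_pvalues.csv",
#'   package = "microskill")`).
#' @return Screening tibble compatible with [select_model_features()]:
#'   `metric`, `hand`, `phase`, `category`, `p`, `significant`.
#' @export
read_screen_pvalues <- function(path) {
  codes <- c(IH = "instrument_handling", RT = "respect_for_tissue",
             Ef = "efficiency", SH = "suture_handling",
             ST = "suturing_technique", QK = "quality_of_knot",
             FP = "final_product", OF = "operation_flow",
             OP = "overall_performance")
  df <- read_csv_checked(path, c("parameter", "phase", names(codes)))
  long <- tidyr::pivot_longer(df, dplyr::all_of(names(codes)),
                              names_to = "code", values_to = "entry")
  mh <- parse_param_label(long$parameter)
  p_chr <- gsub("\\*", "", long$entry)
  lt <- startsWith(p_chr, "<")
  p <- numeric(length(p_chr))
  p[lt] <- as.numeric(sub("<", "", p_chr[lt])) / 2
  p[!lt] <- as.numeric(p_chr[!lt])
  tibble::tibble(metric = mh$metric, hand = mh$hand, phase = long$phase,
                 category = unname(codes[long$code]), p = p,
                 significant = grepl("\\*", long$entry))
}
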