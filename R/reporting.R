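#' Repeat a pipeline over seeds and summarize mean and SD
#'
#' Runs `pipeline(seed)` once per seed (the full tune + refit + test
#' pipeline, or any function returning a named numeric metric vector) and
#' reports per-metric mean and sample standard deviation (n - 1
#' denominator). A failing run is excluded with a warning and recorded in
#' `failed_seeds`.
#'
#' @param pipeline function taking a single integer seed and returning a
#'   named numeric vector (e.g. accuracy, precision, recall, f1,
#'   objective).
#' @param seeds integer vector of seeds (default five runs).
#' @param name label for the optimizer/pipeline being repeated.
#' @return Object of class `run_report`: `name`, `per_run` (data.frame with
#'   a `seed` column), `summary` (metric, mean, sd), `failed_seeds`.
#' @export
repeated_runs <- function(pipeline, seeds = 1:5, name = "AO-HHO") {
  rows <- list()
  failed <- integer(0)
  for (s in seeds) {
    res <- tryCatch(pipeline(s), error = function(e) {
      warning("run with seed ", s, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) { failed <- c(failed, s); next }
    rows[[length(rows) + 1L]] <- c(seed = s, res)
  }
  if (length(rows) == 0L) stop("all runs failed")
  per_run <- as.data.frame(do.call(rbind, rows))
  metrics <- setdiff(names(per_run), "seed")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_run[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_run[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(name = name, per_run = per_run, summary = summary,
                 failed_seeds = failed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report '%s' over %d run(s):\n", x$name, nrow(x$per_run)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %s\n", s$metric[i], format_mean_sd(s$mean[i], s$sd[i])))
  if (length(x$failed_seeds))
    cat("  failed seeds:", paste(x$failed_seeds, collapse = ", "), "\n")
  invisible(x)
}

#' Format a mean and SD as "m ± s"
#'
#' @param m,s mean and standard deviation.
#' @param digits decimal places.
#' @return Character scalar like `"0.8734 ± 0.0052"`.
#' @export
format_mean_sd <- function(m, s, digits = 4) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
}

#' Paired (or Welch) comparison of two metric vectors
#'
#' Mean difference `mean(a) - mean(b)` with a two-sided t-test and 95%
#' confidence interval; in paired mode runs are paired by shared seed and
#' the t-distribution is applied to the differences. When the paired
#' differences have zero variance the test statistic is undefined; the
#' degenerate case is reported as p = 1 (identical vectors) or p = 0
#' (constant nonzero difference) with a zero-width interval.
#'
#' @param a,b numeric vectors of per-run metric values (equal length when
#'   paired, length >= 2).
#' @param paired pair runs by position/seed (default `TRUE`).
#' @param metric_name,comparison_label optional labels carried in the
#'   result.
#' @param conf_level confidence level for the interval.
#' @return Object of class `pairwise_test_result` with `mean_difference`,
#'   `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
pairwise_test <- function(a, b, paired = TRUE, metric_name = NA_character_,
                          comparison_label = NA_character_,
                          conf_level = 0.95) {
  if (paired && length(a) != length(b)) stop("paired vectors must have equal length")
  stopifnot(length(a) >= 2, length(b) >= 2)
  md <- mean(a) - mean(b)
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      p <- if (md == 0) 1 else 0
      ci <- c(md, md)
    } else {
      tt <- stats::t.test(d, conf.level = conf_level)
      p <- tt$p.value
      ci <- as.numeric(tt$conf.int)
    }
  } else {
    tt <- stats::t.test(a, b, conf.level = conf_level)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  structure(list(metric_name = metric_name,
                 comparison_label = comparison_label,
                 mean_difference = md, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n = length(a)),
            class = "pairwise_test_result")
}

#' @export
print.pairwise_test_result <- function(x, ...) {
  cat(sprintf("%s %s: mean diff %.4f, 95%% CI [%.4f, %.4f], p = %.4g (n = %d)\n",
              if (is.na(x$metric_name)) "" else x$metric_name,
              if (is.na(x$comparison_label)) "" else x$comparison_label,
              x$mean_difference, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Standard benchmark test functions
#'
#' Validation oracles for the optimizer stack: sphere and Rastrigin on the
#' classic De Jong box [-5.12, 5.12]^D (optimum 0 at the origin) and
#' Rosenbrock on [-2.048, 2.048]^D (optimum 0 at the all-ones point).
#'
#' @param dimension problem dimension.
#' @return Named list of `benchmark_function` objects, each with `name`,
#'   `dimension`, `fn`, `bounds`, `optimum_location`, `optimum_value`.
#' @export
benchmark_suite <- function(dimension = 5L) {
  dimension <- as.integer(dimension)
  make <- function(name, fn, half_width, opt_loc) {
    structure(list(name = name, dimension = dimension, fn = fn,
                   bounds = search_bounds(dimension, -half_width, half_width),
                   optimum_location = opt_loc,
                   optimum_value = fn(opt_loc)),
              class = "benchmark_function")
  }
  list(
    sphere = make("sphere", function(x) sum(x ^ 2), 5.12, rep(0, dimension)),
    rastrigin = make("rastrigin",
                     function(x) 10 * length(x) + sum(x ^ 2 - 10 * cos(2 * pi * x)),
                     5.12, rep(0, dimension)),
    rosenbrock = make("rosenbrock",
                      function(x) sum(100 * (x[-1] - x[-length(x)] ^ 2) ^ 2 +
                                        (1 - x[-length(x)]) ^ 2),
                      2.048, rep(1, dimension)))
}

#' Write the report tables and convergence data to a directory
#'
#' Emits deterministic CSV files: point metrics per optimizer, formatted
#' mean +/- SD, pairwise tests of the first (reference) report against the
#' others (paired by seed), optional ablation and evaluation-cost tables,
#' per-run convergence traces and confusion matrices. Re-emitting from the
#' same inputs is byte-identical. Set `plots = TRUE` to also write PNG
#' convergence-curve plots. A footnote file records that the pairwise
#' p-values are raw (no multiple-testing correction).
#'
#' @param reports list of [repeated_runs()] results; the first is the
#'   reference for pairwise comparisons.
#' @param out_dir output directory (created if needed).
#' @param ablation optional data.frame (e.g. `ablate()$summary`).
#' @param cost optional data.frame of evaluation counts / time measures.
#' @param histories optional named list of convergence data.frames
#'   (iteration, phase, best_objective).
#' @param confusions optional named list of confusion matrices.
#' @param plots write PNG convergence plots.
#' @return Invisibly, the written file paths.
#' @export
emit_report <- function(reports, out_dir, ablation = NULL, cost = NULL,
                        histories = NULL, confusions = NULL, plots = FALSE) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("at least one run report is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  w <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  names(reports) <- vapply(reports, `[[`, character(1), "name")
  metrics <- reports[[1]]$summary$metric

  point <- data.frame(Metric = metrics, stringsAsFactors = FALSE)
  for (r in reports) point[[r$name]] <- r$summary$mean[match(metrics, r$summary$metric)]
  w(point, "point_metrics.csv")

  meansd <- data.frame(Optimizer = names(reports), stringsAsFactors = FALSE)
  for (m in metrics)
    meansd[[m]] <- vapply(reports, function(r) {
      i <- match(m, r$summary$metric)
      format_mean_sd(r$summary$mean[i], r$summary$sd[i])
    }, character(1))
  w(meansd, "mean_sd.csv")

  if (length(reports) > 1L) {
    rows <- list()
    ref <- reports[[1]]
    for (m in metrics)
      for (other in reports[-1]) {
        pt <- pairwise_test(ref$per_run[[m]], other$per_run[[m]],
                            paired = TRUE, metric_name = m,
                            comparison_label = paste(ref$name, "vs.", other$name))
        rows[[length(rows) + 1L]] <- data.frame(
          Metric = m, Comparison = pt$comparison_label,
          Mean_difference = pt$mean_difference,
          CI_lower = pt$ci_low, CI_upper = pt$ci_high,
          p_value = pt$p_value, stringsAsFactors = FALSE)
      }
    w(do.call(rbind, rows), "pairwise_tests.csv")
    writeLines("p-values are raw two-sided paired t-tests; no multiple-testing correction applied.",
               file.path(out_dir, "pairwise_tests_footnote.txt"))
    written <- c(written, file.path(out_dir, "pairwise_tests_footnote.txt"))
  }

  if (!is.null(ablation)) w(ablation, "ablation.csv")
  if (!is.null(cost)) w(cost, "evaluation_cost.csv")
  for (nm in names(histories))
    w(histories[[nm]], sprintf("convergence_%s.csv", gsub("\\W+", "_", nm)))
  for (nm in names(confusions)) {
    cm <- as.data.frame(unclass(as.matrix(confusions[[nm]])))
    cm <- cbind(true_class = rownames(cm), cm)
    w(cm, sprintf("confusion_%s.csv", gsub("\\W+", "_", nm)))
  }
  if (plots && length(histories)) {
    p <- file.path(out_dir, "convergence.png")
    grDevices::png(p, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    ylim <- range(unlist(lapply(histories, `[[`, "best_objective")))
    graphics::plot(NULL, xlim = c(1, max(vapply(histories, nrow, integer(1)))),
                   ylim = ylim, xlab = "iteration", ylab = "best objective",
                   main = "Convergence")
    for (i in seq_along(histories))
      graphics::lines(histories[[i]]$iteration,
                      histories[[i]]$best_objective, col = i, lwd = 2)
    graphics::legend("topright", legend = names(histories),
                     col = seq_along(histories), lwd = 2)
    written <- c(written, p)
  }
  invisible(written)
}
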