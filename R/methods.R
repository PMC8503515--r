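# S3 methods for ancestral_spectrum objects.

#' @export
print.ancestral_spectrum <- function(x, ...) {
  cat("Ancestral spectrum:", nrow(x$info), "individuals,",
      length(x$pops), "reference populations (",
      paste(x$pops, collapse = ", "), ")\n")
  cat("Panel SNPs per population:",
      paste(sprintf("%s=%d", names(x$panel_sizes), x$panel_sizes),
            collapse = ", "), "\n")
  cat("Mean ancestral information:\n")
  print(round(colMeans(x$info), 4))
  cat("Mean total information:", round(mean(x$total_info), 4), "\n")
  if (!is.null(x$mle))
    cat("MLE computed;", sum(x$boundary), "boundary solution(s)\n")
  invisible(x)
}

#' Extract ancestral proportion estimates
#'
#' The ancestral information matrix (the BLUE of the ancestral proportions)
#' is the object's coefficient matrix.
#'
#' @param object an `ancestral_spectrum` fit.
#' @param which `"info"` (default), `"scores"` or `"mle"`.
#' @param ... unused.
#' @return N x K numeric matrix.
#' @export
coef.ancestral_spectrum <- function(object,
                                    which = c("info", "scores", "mle"),
                                    ...) {
  which <- match.arg(which)
  if (which == "mle" && is.null(object$mle))
    stop("fit was computed without mle = TRUE")
  object[[which]]
}

#' Flatten a fit to a results table
#'
#' One row per individual with columns `SAMPLE`, `SCORE_<pop>`,
#' `INFO_<pop>`, optionally `MLE_<pop>`, then `TOTAL_INFO` and `CALLRATE`.
#'
#' @param x an `ancestral_spectrum` fit.
#' @param row.names,optional,... passed through for S3 compatibility, unused.
#' @return A data frame in input sample order.
#' @export
as.data.frame.ancestral_spectrum <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  out <- data.frame(SAMPLE = rownames(x$info), stringsAsFactors = FALSE)
  sc <- x$scores; colnames(sc) <- paste0("SCORE_", x$pops)
  inf <- x$info; colnames(inf) <- paste0("INFO_", x$pops)
  out <- cbind(out, sc, inf)
  if (!is.null(x$mle)) {
    ml <- x$mle; colnames(ml) <- paste0("MLE_", x$pops)
    out <- cbind(out, ml)
  }
  out$TOTAL_INFO <- x$total_info
  out$CALLRATE <- x$call_rate
  rownames(out) <- NULL
  out
}

#' Per-population summary of ancestral spectra
#'
#' Groups individuals by a population assignment (all one group when absent)
#' and reports the mean and standard deviation of each ancestral information
#' component and of the total information. Individuals whose information
#' vector deviates from their group mean by more than `outlier_sd` group
#' standard deviations in any component are flagged as genetic outliers.
#' Groups of one individual have undefined standard deviations, reported as
#' `NA`, and yield no outlier calls.
#'
#' @param object an `ancestral_spectrum` fit.
#' @param assignment optional data frame with columns `sample`, `pop`.
#' @param outlier_sd flagging threshold in group standard deviations.
#' @param ... unused.
#' @return Object of class `"summary.ancestral_spectrum"`: a list with
#'   `stats` (group x population means/sds) and `outliers` (data frame of
#'   flagged individuals).
#' @export
summary.ancestral_spectrum <- function(object, assignment = NULL,
                                       outlier_sd = 4, ...) {
  samples <- rownames(object$info)
  group <- if (is.null(assignment)) rep("all", length(samples)) else {
    check_assignment(assignment)
    assignment$pop[match(samples, assignment$sample)]
  }
  group[is.na(group)] <- "unassigned"
  vals <- cbind(object$info, TOTAL = object$total_info)
  stats_list <- lapply(split(seq_along(samples), group), function(i) {
    v <- vals[i, , drop = FALSE]
    list(n = length(i), mean = colMeans(v),
         sd = if (length(i) > 1) apply(v, 2, stats::sd)
              else rep(NA_real_, ncol(v)))
  })
  gs <- names(stats_list)
  stat_rows <- do.call(rbind, lapply(gs, function(g) {
    s <- stats_list[[g]]
    data.frame(group = g, n = s$n, component = colnames(vals),
               mean = unname(s$mean), sd = unname(s$sd),
               stringsAsFactors = FALSE)
  }))
  rownames(stat_rows) <- NULL

  flags <- lapply(gs, function(g) {
    s <- stats_list[[g]]
    if (s$n < 2 || any(is.na(s$sd))) return(NULL)
    i <- which(group == g)
    dev <- abs(sweep(object$info[i, , drop = FALSE], 2,
                     s$mean[object$pops], "-"))
    sdv <- s$sd[object$pops]
    sdv[sdv == 0] <- Inf                 # constant component: never an outlier
    z <- sweep(dev, 2, sdv, "/")
    hit <- apply(z, 1, max) > outlier_sd
    if (!any(hit)) return(NULL)
    data.frame(sample = samples[i][hit], group = g,
               max_sd = apply(z, 1, max)[hit], stringsAsFactors = FALSE)
  })
  outliers <- do.call(rbind, flags)
  if (is.null(outliers))
    outliers <- data.frame(sample = character(0), group = character(0),
                           max_sd = numeric(0), stringsAsFactors = FALSE)
  structure(list(stats = stat_rows, outliers = outliers,
                 outlier_sd = outlier_sd),
            class = "summary.ancestral_spectrum")
}

#' @export
print.summary.ancestral_spectrum <- function(x, ...) {
  cat("Group summary of ancestral information:\n")
  print(x$stats, digits = 4)
  if (nrow(x$outliers)) {
    cat("\nGenetic outliers (>", x$outlier_sd, "group SDs):\n")
    print(x$outliers, digits = 3)
  } else {
    cat("\nNo genetic outliers at", x$outlier_sd, "group SDs.\n")
  }
  invisible(x)
}

#' Plot ancestral spectra
#'
#' Stacked bars of the K ancestral information components, one bar per
#' individual — the usual admixture-style display. Bars may exceed one:
#' total information is deliberately unconstrained.
#'
#' @param x an `ancestral_spectrum` fit.
#' @param col bar colours, one per reference population.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.ancestral_spectrum <- function(x, col = NULL, ...) {
  if (is.null(col)) col <- grDevices::hcl.colors(length(x$pops), "Dark 3")
  mids <- graphics::barplot(t(x$info), col = col, border = NA,
                            space = 0, las = 2,
                            ylab = "ancestral information", ...)
  graphics::legend("topright", legend = x$pops, fill = col, bty = "n")
  invisible(mids)
}
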