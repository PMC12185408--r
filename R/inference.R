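# Statistical validation and grouping of deformation records.

#' Distributional validation of initial shape features
#'
#' Shapiro-Wilk normality tests on initial area and perimeter (and
#' elongation when present), and a Kolmogorov-Smirnov uniformity test on
#' the initial angle against the stated angle range. These are descriptive
#' checks of the generator/experiment assumptions; no multiple-testing
#' correction is applied. A constant-valued feature yields a per-feature
#' degenerate-input entry rather than an exception.
#'
#' @param records data frame with `A_initial_um2`, `perimeter_um`,
#'   `angle_deg` and optionally `elongation`.
#' @param alpha significance level for the pass flags.
#' @param angle_range uniformity support for the angle test (degrees).
#' @return Data frame (class `"distribution_report"`) with columns
#'   `feature`, `test`, `p_value`, `pass`, `note`.
#' @export
test_distributions <- function(records, alpha = 0.01, angle_range = c(0, 180)) {
  if (nrow(records) < 8L) stop("need at least 8 records")
  feat <- list(
    area = list(x = records$A_initial_um2, test = "shapiro"),
    perimeter = list(x = records$perimeter_um, test = "shapiro"),
    angle = list(x = records$angle_deg, test = "ks_uniform"))
  if (!is.null(records$elongation))
    feat$elongation <- list(x = records$elongation, test = "shapiro")
  rows <- lapply(names(feat), function(nm) {
    x <- feat[[nm]]$x
    tst <- feat[[nm]]$test
    if (is.null(x) || length(unique(x)) == 1L)
      return(data.frame(feature = nm, test = tst, p_value = NA_real_,
                        pass = NA, note = "degenerate: constant feature"))
    pv <- if (tst == "shapiro") stats::shapiro.test(x)$p.value
          else stats::ks.test(x, "punif", angle_range[1L], angle_range[2L])$p.value
    data.frame(feature = nm, test = tst, p_value = pv, pass = pv >= alpha,
               note = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("distribution_report", "data.frame")
  out
}

#' Group records by peak pressure
#'
#' Sorts records by `pmax_kPa` and accretes them greedily left-to-right
#' into pressure levels. A candidate joins the current group only while the
#' group's coefficient of variation stays at or below `cv_max` *and* the
#' candidate lies within `cv_max` of the running group mean (the
#' "group-internal pressure variation below 5 percent" rule; the second
#' condition keeps adjacent printed levels from fusing). Closed groups
#' smaller than `min_size` ("more than three data points") go to the
#' ungrouped residue. The procedure is deterministic after sorting, hence
#' permutation-invariant.
#'
#' @param records data frame with a `pmax_kPa` column.
#' @param cv_max maximum coefficient of variation within a group.
#' @param min_size minimum admissible group size.
#' @return Object of class `"pressure_grouping"`: `groups` (data frame
#'   `label`, `mean_pmax`, `sd_pmax`, `n`), `assignment` (per input record:
#'   a group label or `NA` for the residue) and `records` (input augmented
#'   with the assignment as `pressure_group`).
#' @export
group_by_pressure <- function(records, cv_max = 0.05, min_size = 4L) {
  stopifnot(!is.null(records$pmax_kPa), all(is.finite(records$pmax_kPa)))
  ord <- order(records$pmax_kPa)
  p <- records$pmax_kPa[ord]
  n <- length(p)
  gid <- integer(n)
  cur <- 1L
  members <- p[1L]
  gid[1L] <- cur
  for (i in seq_len(n)[-1L]) {
    cand <- c(members, p[i])
    m <- mean(cand)
    cv <- stats::sd(cand) / m
    dev <- abs(p[i] - mean(members)) / mean(members)
    if (cv <= cv_max && dev <= cv_max) {
      members <- cand
    } else {
      cur <- cur + 1L
      members <- p[i]
    }
    gid[i] <- cur
  }
  sizes <- tabulate(gid)
  keep <- which(sizes >= min_size)
  label_of <- rep(NA_character_, max(gid))
  label_of[keep] <- paste0("Lvl", seq_along(keep))
  assignment <- rep(NA_character_, n)
  assignment[ord] <- label_of[gid]
  groups <- do.call(rbind, lapply(seq_along(keep), function(k) {
    v <- p[gid == keep[k]]
    data.frame(label = paste0("Lvl", k), mean_pmax = mean(v),
               sd_pmax = stats::sd(v), n = length(v))
  }))
  if (is.null(groups))
    groups <- data.frame(label = character(0), mean_pmax = numeric(0),
                         sd_pmax = numeric(0), n = integer(0))
  recs <- records
  recs$pressure_group <- assignment
  structure(list(groups = groups, assignment = assignment, records = recs,
                 cv_max = cv_max, min_size = min_size),
            class = "pressure_grouping")
}

#' @export
print.pressure_grouping <- function(x, ...) {
  cat(sprintf("Pressure grouping: %d groups, %d records grouped, %d ungrouped\n",
              nrow(x$groups), sum(!is.na(x$assignment)),
              sum(is.na(x$assignment))))
  print(transform(x$groups, mean_pmax = signif(mean_pmax, 5),
                  sd_pmax = signif(sd_pmax, 4)), row.names = FALSE)
  invisible(x)
}

#' Per-group linear fits of zeta against initial area
#'
#' Ordinary least squares of `zeta ~ A_initial` within each pressure group;
#' the fitted lines expose how initial size suppresses the deformation
#' ratio at each pressure level. Groups without at least two distinct
#' initial areas produce a per-group error entry.
#'
#' @param grouping a [group_by_pressure()] result.
#' @return Data frame with `label`, `mean_pmax`, `n`, `slope`, `intercept`,
#'   `r_squared`, `error`.
#' @export
fit_group_lines <- function(grouping) {
  stopifnot(inherits(grouping, "pressure_grouping"))
  recs <- grouping$records
  rows <- lapply(seq_len(nrow(grouping$groups)), function(k) {
    lab <- grouping$groups$label[k]
    d <- recs[!is.na(recs$pressure_group) & recs$pressure_group == lab, ]
    base <- data.frame(label = lab, mean_pmax = grouping$groups$mean_pmax[k],
                       n = nrow(d), slope = NA_real_, intercept = NA_real_,
                       r_squared = NA_real_, error = "")
    if (length(unique(d$A_initial_um2)) < 2L) {
      base$error <- "degenerate A_initial spread"
      return(base)
    }
    fit <- stats::lm(zeta ~ A_initial_um2, data = d)
    base$slope <- unname(stats::coef(fit)[2L])
    base$intercept <- unname(stats::coef(fit)[1L])
    sst <- sum((d$zeta - mean(d$zeta))^2)
    base$r_squared <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst
                      else NA_real_
    base
  })
  do.call(rbind, rows)
}

#' Count area-shrinking records
#'
#' Cells with `zeta < 1` shrank under loading -- the signature of outward
#' water exchange through membrane pores (mass non-conservation).
#'
#' @param records data frame with a `zeta` column.
#' @return List with `count` and `fraction`.
#' @export
count_shrinking <- function(records) {
  n <- nrow(records)
  cnt <- sum(records$zeta < 1)
  list(count = cnt, fraction = if (n > 0) cnt / n else NA_real_)
}
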