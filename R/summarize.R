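## (mean, SE, SD, denominator) over a numeric vector; NA-safe for empty input
msd <- function(x) {
  n <- length(x)
  if (n == 0L) return(c(mean = NA_real_, se = NA_real_, sd = NA_real_,
                        denom = 0))
  s <- if (n > 1L) stats::sd(x) else 0
  c(mean = mean(x), se = s / sqrt(n), sd = s, denom = n)
}

summary_row <- function(band, n, group, stat, trip) {
  if (!"denom" %in% names(trip)) trip["denom"] <- n
  data.frame(band_lo = band[1], band_hi = band[2], n = n, group = group,
             stat = stat, mean = unname(trip["mean"]), se = unname(trip["se"]),
             sd = unname(trip["sd"]), denom = unname(trip["denom"]),
             stringsAsFactors = FALSE)
}

arm_band_rows <- function(band, arm, o, extra_pad = FALSE) {
  n <- nrow(o)
  rows <- list()
  add <- function(stat, trip) {
    rows[[length(rows) + 1L]] <<- summary_row(band, n, arm, stat, trip)
  }
  if (arm == "EPO") add("hb_change", msd(o$hb_change))
  if (extra_pad) {
    add("hb_change", msd(-o$hb_change[o$pad_applicable]))
    add("transfused_autologous_pct", msd(100 * (o$autologous_units > 0)))
    add("units_per_autologous_transfused",
        msd(o$autologous_units[o$autologous_units > 0]))
    add("transfused_allogeneic_pct", msd(100 * (o$allogeneic_units > 0)))
    add("units_per_allogeneic_transfused",
        msd(o$allogeneic_units[o$allogeneic_units > 0]))
  }
  add("transfused_pct", msd(100 * o$transfused))
  add("units_per_transfused", msd(o$units_needed[o$transfused]))
  add("infection_pct", msd(100 * o$infection))
  add("mean_los", msd(o$los))
  for (cc in c("epo_cost", "transfusion_allogeneic_cost",
               "pad_collection_cost", "los_cost", "pneumonia_cost",
               "total_cost")) {
    add(cc, msd(o[[cc]]))
  }
  do.call(rbind, rows)
}

#' Stratify a run by baseline-hemoglobin band and summarize
#'
#' Reproduces the banded reporting layout of the model: patients are grouped
#' into half-open 0.5 g/dl baseline-Hb bands from 10.0 to 13.0 g/dl, and for
#' each band the baseline characteristics, per-arm clinical/resource/cost
#' statistics and the paired incremental total costs (ABT minus EPO, PAD
#' minus EPO) are reported as (mean, SE, SD) with SE = SD/sqrt(n).
#' Autologous-donation columns are suppressed (NA) for bands below 11 g/dl,
#' where donation is not indicated. When the run's configuration selects the
#' revision subgroup, all summaries are restricted to revision patients.
#'
#' @param run a \code{bloodsim_run}.
#' @param band_lo lower edges of the half-open bands \code{[lo, lo + width)}.
#' @param width band width in g/dl.
#' @param include_overall also append an unstratified band covering every
#'   patient (full-population output).
#' @return A long-format \code{data.frame} of class \code{bloodsim_summary}
#'   with columns \code{band_lo}, \code{band_hi}, \code{n}, \code{group}
#'   (\code{baseline}, one of the arms, or \code{incremental}), \code{stat},
#'   \code{mean}, \code{se}, \code{sd} and \code{denom}, the denominator the
#'   mean and SE were computed over (the band count for most rows, the
#'   full cohort for \code{pct_of_total}, transfused patients only for
#'   units-per-transfusion rows).
#' @export
stratify_and_summarize <- function(run, band_lo = seq(10, 12.5, by = 0.5),
                                   width = 0.5, include_overall = FALSE) {
  pts <- run$patients
  out <- run$outcomes
  if (identical(run$config$subset, "revision")) {
    keep <- pts$patient_id[pts$revision]
    pts <- pts[pts$revision, ]
    out <- out[out$patient_id %in% keep, ]
  }
  if (nrow(pts) == 0L) stop("no patients to summarize", call. = FALSE)
  n_total <- nrow(pts)

  bands <- cbind(lo = band_lo, hi = band_lo + width)
  if (include_overall) bands <- rbind(bands, c(-Inf, Inf))

  pieces <- list()
  for (b in seq_len(nrow(bands))) {
    band <- bands[b, ]
    in_band <- pts$baseline_hb >= band[1] & pts$baseline_hb < band[2]
    bp <- pts[in_band, ]
    n <- nrow(bp)

    base_rows <- rbind(
      summary_row(band, n, "baseline", "pct_of_total",
                  msd(100 * as.numeric(in_band))),
      summary_row(band, n, "baseline", "female_pct",
                  msd(100 * (bp$sex == "female"))),
      summary_row(band, n, "baseline", "age", msd(bp$age)),
      summary_row(band, n, "baseline", "revision_pct",
                  msd(100 * bp$revision)),
      summary_row(band, n, "baseline", "hip_pct",
                  msd(100 * (bp$procedure == "hip"))),
      summary_row(band, n, "baseline", "asa_ge3_pct",
                  msd(100 * bp$asa_ge3)),
      summary_row(band, n, "baseline", "cardiac_pct",
                  msd(100 * bp$cardiac_history)),
      summary_row(band, n, "baseline", "baseline_hb", msd(bp$baseline_hb))
    )
    pieces[[length(pieces) + 1L]] <- base_rows
    if (n == 0L) {
      # empty band: arm and incremental cells become missing markers
      empty <- out[0, ]
      for (arm in ARM_NAMES) {
        pieces[[length(pieces) + 1L]] <-
          arm_band_rows(band, arm, empty, extra_pad = (arm == "PAD"))
      }
      for (st in c("ABT_minus_EPO_total", "PAD_minus_EPO_total")) {
        pieces[[length(pieces) + 1L]] <-
          summary_row(band, n, "incremental", st,
                      c(mean = NA_real_, se = NA_real_, sd = NA_real_,
                        denom = 0))
      }
      next
    }

    ids <- bp$patient_id
    pad_allowed <- band[1] >= 11 || is.infinite(band[1])
    totals <- list()
    for (arm in ARM_NAMES) {
      oa <- out[out$arm == arm & out$patient_id %in% ids, ]
      oa <- oa[order(oa$patient_id), ]
      totals[[arm]] <- oa$total_cost
      if (arm == "PAD" && !pad_allowed) {
        blank <- arm_band_rows(band, arm, oa, extra_pad = TRUE)
        blank[, c("mean", "se", "sd", "denom")] <- NA_real_
        pieces[[length(pieces) + 1L]] <- blank
      } else {
        pieces[[length(pieces) + 1L]] <-
          arm_band_rows(band, arm, oa, extra_pad = (arm == "PAD"))
      }
    }
    if (n >= 2L) {
      inc_ae <- incremental_cost(totals$ABT, totals$EPO)
      pieces[[length(pieces) + 1L]] <-
        summary_row(band, n, "incremental", "ABT_minus_EPO_total",
                    inc_ae[c("mean", "se", "sd")])
      inc_pe <- if (pad_allowed) {
        incremental_cost(totals$PAD, totals$EPO)[c("mean", "se", "sd")]
      } else {
        c(mean = NA_real_, se = NA_real_, sd = NA_real_)
      }
      pieces[[length(pieces) + 1L]] <-
        summary_row(band, n, "incremental", "PAD_minus_EPO_total", inc_pe)
    }
  }
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  attr(res, "scenario") <- run$config$name
  attr(res, "n_total") <- n_total
  class(res) <- c("bloodsim_summary", "data.frame")
  res
}

#' @export
print.bloodsim_summary <- function(x, stats = c("transfused_pct",
                                                "mean_los", "total_cost"), ...) {
  cat(sprintf("<bloodsim_summary> scenario '%s' (%d patients)\n",
              attr(x, "scenario"), attr(x, "n_total")))
  df <- as.data.frame(x)
  bands <- unique(df[, c("band_lo", "band_hi")])
  lab <- ifelse(is.finite(bands$band_lo),
                sprintf("%.1f-%.1f", bands$band_lo, bands$band_hi), "all")
  hdr <- sprintf("%-28s", "stat / Hb band")
  cat(hdr, paste(sprintf("%9s", lab), collapse = " "), "\n")
  ns <- vapply(seq_len(nrow(bands)), function(i) {
    df$n[df$band_lo %in% bands$band_lo[i] & df$band_hi %in% bands$band_hi[i]][1]
  }, numeric(1))
  cat(sprintf("%-28s", "n"), paste(sprintf("%9d", as.integer(ns)),
                                   collapse = " "), "\n")
  for (grp in c("ABT", "PAD", "EPO")) {
    for (st in stats) {
      vals <- vapply(seq_len(nrow(bands)), function(i) {
        v <- df$mean[df$group == grp & df$stat == st &
                     df$band_lo %in% bands$band_lo[i] &
                     df$band_hi %in% bands$band_hi[i]]
        if (length(v)) v[1] else NA_real_
      }, numeric(1))
      cat(sprintf("%-28s", paste(grp, st)),
          paste(sprintf("%9.1f", vals), collapse = " "), "\n")
    }
  }
  for (st in c("ABT_minus_EPO_total", "PAD_minus_EPO_total")) {
    vals <- vapply(seq_len(nrow(bands)), function(i) {
      v <- df$mean[df$group == "incremental" & df$stat == st &
                   df$band_lo %in% bands$band_lo[i] &
                   df$band_hi %in% bands$band_hi[i]]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    cat(sprintf("%-28s", st), paste(sprintf("%9.1f", vals), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.bloodsim_summary <- function(x, stat = "transfused_pct",
                                  ylab = "Transfused [%]", ...) {
  df <- as.data.frame(x)
  df <- df[is.finite(df$band_lo) & df$stat == stat &
           df$group %in% ARM_NAMES, ]
  if (nrow(df) == 0L) stop("statistic not present in summary", call. = FALSE)
  bands <- sort(unique(df$band_lo))
  cols <- c(ABT = "firebrick", PAD = "steelblue", EPO = "forestgreen")
  ylim <- range(df$mean, na.rm = TRUE)
  graphics::plot(NA, xlim = range(bands), ylim = ylim,
                 xlab = "Baseline Hb band (lower edge, g/dl)", ylab = ylab,
                 main = attr(x, "scenario"), ...)
  for (arm in ARM_NAMES) {
    sub <- df[df$group == arm, ]
    sub <- sub[order(sub$band_lo), ]
    graphics::lines(sub$band_lo, sub$mean, type = "b", pch = 16,
                    col = cols[[arm]])
  }
  graphics::legend("topright", legend = ARM_NAMES, col = cols[ARM_NAMES],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Run the full sensitivity-scenario grid
#'
#' Executes every scenario from [build_scenarios()] (or a supplied subset)
#' with the same master seed, so patient characteristics are common random
#' numbers across scenarios and scenario deltas are not dominated by
#' sampling noise.
#'
#' @param base_config a validated \code{bloodsim_config}.
#' @param scenarios named list of scenario specs; defaults to the full grid.
#' @param n_patients optional patient-count override applied to every
#'   scenario.
#' @return A named list of \code{bloodsim_summary} objects, one per
#'   scenario, of class \code{bloodsim_grid}.
#' @export
run_scenario_grid <- function(base_config, scenarios = NULL,
                              n_patients = NULL) {
  if (is.null(scenarios)) scenarios <- build_scenarios(base_config)
  res <- lapply(scenarios, function(s) {
    cfg <- apply_scenario(base_config, s)
    stratify_and_summarize(run_simulation(cfg, n_patients = n_patients))
  })
  names(res) <- vapply(scenarios, `[[`, "", "name")
  class(res) <- "bloodsim_grid"
  res
}

summary_to_list <- function(s) {
  list(scenario = attr(s, "scenario"), n_total = attr(s, "n_total"),
       cells = as.data.frame(s))
}

list_to_summary <- function(l) {
  df <- as.data.frame(l$cells, stringsAsFactors = FALSE)
  for (cc in c("band_lo", "band_hi", "n", "mean", "se", "sd", "denom")) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  attr(df, "scenario") <- l$scenario
  attr(df, "n_total") <- l$n_total
  class(df) <- c("bloodsim_summary", "data.frame")
  df
}

#' Write banded summaries to CSV and JSON report files
#'
#' Writes one CSV per scenario mirroring the banded row/column layout
#' (long format, (mean, SE, SD) per cell; empty-band cells are missing
#' markers, not zeros) plus a machine-readable JSON of every cell. The JSON
#' round-trips through [read_report()].
#'
#' @param summaries a \code{bloodsim_summary} or a (possibly named) list of
#'   them, e.g. a \code{bloodsim_grid}.
#' @param path output directory; created if missing.
#' @return Invisibly, the paths of the written files.
#' @export
write_report <- function(summaries, path) {
  if (inherits(summaries, "bloodsim_summary")) {
    summaries <- stats::setNames(list(summaries), attr(summaries, "scenario"))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create report directory: ", path,
                              call. = FALSE)
  files <- character()
  for (nm in names(summaries)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(summaries[[nm]]), f, row.names = FALSE,
                     na = "")
    files <- c(files, f)
  }
  jf <- file.path(path, "report.json")
  jsonlite::write_json(lapply(unclass(summaries), summary_to_list), jf,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(c(files, jf))
}

#' Re-load a JSON report written by [write_report()]
#'
#' @param path the report directory.
#' @return A named list of \code{bloodsim_summary} objects.
#' @export
read_report <- function(path) {
  jf <- file.path(path, "report.json")
  if (!file.exists(jf)) stop("no report.json under ", path, call. = FALSE)
  raw <- jsonlite::read_json(jf, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  lapply(raw, list_to_summary)
}
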