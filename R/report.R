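# Group-level statistics and the end-to-end report driver.

#' Group summary table with rank-sum tests against the control group
#'
#' Per-group mean and standard error for each metric, with a Mann-Whitney
#' rank-sum test of every non-control group against the control group.
#' Significance marks follow the two-tier convention `*` p < 0.001 and
#' `**` p < 0.05. No multiple-testing correction is applied; raw p-values
#' are reported.
#'
#' @param profiles data.frame of patient profiles with a `group` column.
#' @param control_label Which group supplies the reference distribution.
#' @param metrics Metric columns to summarise.
#' @param test `"wilcoxon"` (default, the rank-sum test) or `"t"` for
#'   Student's t.
#' @return data.frame `group, n, metric, mean, se, p_value, mark`; groups
#'   with fewer than 2 values are summarised without SE or test and flagged
#'   by `mark = "(n<2)"`.
#' @export
summarize_groups <- function(profiles, control_label = "control",
                             metrics = c("dg_per_platelet",
                                         "mean_diameter_nm",
                                         "mdgv_nm3", "tdgv_nm3"),
                             test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot("group" %in% names(profiles))
  groups <- unique(profiles$group)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (!control_label %in% groups) {
    stop("control group '", control_label, "' absent", call. = FALSE)
  }
  rows <- list()
  for (g in groups) {
    sub <- profiles[profiles$group == g, , drop = FALSE]
    for (mt in metrics) {
      x <- sub[[mt]]
      x <- x[is.finite(x)]
      n <- length(x)
      if (n < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g, n = n, metric = mt,
          mean = if (n) mean(x) else NA_real_, se = NA_real_,
          p_value = NA_real_, mark = "(n<2)")
        next
      }
      p <- NA_real_
      if (g != control_label) {
        ctrl <- profiles[[mt]][profiles$group == control_label]
        ctrl <- ctrl[is.finite(ctrl)]
        if (length(ctrl) >= 2) {
          p <- if (test == "wilcoxon") {
            stats::wilcox.test(x, ctrl, exact = FALSE, correct = FALSE)$p.value
          } else {
            stats::t.test(x, ctrl)$p.value
          }
        }
      }
      mark <- if (!is.na(p) && p < 0.001) "*"
        else if (!is.na(p) && p < 0.05) "**" else ""
      rows[[length(rows) + 1]] <- data.frame(
        group = g, n = n, metric = mt, mean = mean(x),
        se = stats::sd(x) / sqrt(n), p_value = p, mark = mark)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between granule count and total granule volume
#'
#' Pearson correlation of DG/PL against TDGV over a pooled subset of
#' groups (the published comparison pools controls and classic
#' dense-granule deficiency).
#'
#' @param profiles Patient profiles with `dg_per_platelet`, `tdgv_nm3` and
#'   optionally `group`.
#' @param groups Optional subset of groups to pool; default uses all rows.
#' @return One-row data.frame `n, r, p_value`; `r` is NA when either
#'   variable has zero variance.
#' @export
count_volume_correlation <- function(profiles, groups = NULL) {
  sub <- profiles
  if (!is.null(groups)) {
    stopifnot("group" %in% names(profiles))
    sub <- profiles[profiles$group %in% groups, , drop = FALSE]
  }
  ok <- is.finite(sub$dg_per_platelet) & is.finite(sub$tdgv_nm3)
  x <- sub$dg_per_platelet[ok]; y <- sub$tdgv_nm3[ok]
  if (length(x) < 3) stop("need >= 3 profiles", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(n = length(x), r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x, y)
  data.frame(n = length(x), r = unname(ct$estimate), p_value = ct$p.value)
}

#' Default end-to-end report configuration
#'
#' Four calibrated groups at demonstration scale plus the measurement and
#' classification settings. `source = "truth"` profiles the simulated truth
#' tables directly; `source = "rendered"` pushes every platelet through the
#' image renderer and detector (slower, exercises the full pipeline).
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_per_group Named vector of cohort sizes.
#' @param source `"truth"` or `"rendered"`.
#' @param platelets_per_patient Platelets enumerated per subject.
#' @export
report_config <- function(out_dir,
                          seed = 1L,
                          n_per_group = c(control = 20, dspd = 20,
                                          mgspd = 20, elevated = 20),
                          source = c("truth", "rendered"),
                          platelets_per_patient = 100) {
  source <- match.arg(source)
  list(out_dir = out_dir, seed = as.integer(seed),
       n_per_group = n_per_group, source = source,
       platelets_per_patient = platelets_per_patient,
       uranaffin = list(type_mix = c(0.55, 0.25, 0.12, 0.08),
                        n_granules = 150))
}

#' Run the full analysis pipeline and write the artifact bundle
#'
#' Stages: simulate the configured cohorts, measure them (from truth tables
#' or rendered images), profile patients, build control reference ranges,
#' classify, summarise groups, type uranaffin sections for control and
#' microgranular cohorts, and simulate-and-correlate nucleotide panels.
#' Any stage failure aborts with the stage name. Outputs (all plain text):
#' `profiles.json`, `labels.csv`, `group_summary.csv`, `reference.json`,
#' `tdgv_separation.csv`, `uranaffin_distribution.csv`,
#' `correlations.csv`, `log.txt`.
#'
#' @param config A [report_config()] list (or a YAML file path holding the
#'   same keys).
#' @return Invisibly, a list with every computed table.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  groups <- names(config$n_per_group)
  profiles <- stage("simulate+profile", {
    if (!"control" %in% groups) {
      stop("no control group configured; reference ranges need controls")
    }
    pieces <- lapply(seq_along(groups), function(i) {
      g <- groups[i]
      spec <- calibrated_cohort_spec(
        g, n_patients = config$n_per_group[[g]],
        platelets_per_patient = config$platelets_per_patient)
      sim <- simulate_cohort(spec, seed = seed + i)
      prof <- if (identical(config$source, "rendered")) {
        truth <- layout_wholemount(sim, seed = seed + 100 + i)
        meas <- measure_wholemount_cohort(truth, seed = seed + 200 + i)
        profile_cohort(meas, seed = seed + 300 + i)
      } else {
        profile_cohort_from_truth(sim, seed = seed + 300 + i)
      }
      prof$group <- g
      prof$patient_id <- sprintf("%s_%03d", g, prof$patient_id)
      prof
    })
    do.call(rbind, pieces)
  })

  ranges <- stage("reference", {
    build_reference(profiles[profiles$group == "control", , drop = FALSE])
  })
  cls <- stage("classify", classify_cohort(profiles, ranges))
  summary_tab <- stage("summarize", summarize_groups(profiles))
  cvc <- stage("correlate", {
    count_volume_correlation(profiles, groups = intersect(
      c("control", "dspd"), groups))
  })

  ur <- stage("uranaffin", {
    mixes <- list(control = config$uranaffin$type_mix,
                  mgspd = config$uranaffin$type_mix)
    fields <- lapply(seq_along(mixes), function(i) {
      sec <- render_uranaffin_section(mixes[[i]], config$uranaffin$n_granules,
                                      seed = seed + 400 + i)
      m <- measure_uranaffin(sec$image)
      tabulate(m$assigned_type, nbins = 4)
    })
    cmp <- compare_type_distributions(fields[[1]], fields[[2]])
    dist_tab <- data.frame(
      group = rep(names(mixes), each = 4),
      type = rep(1:4, times = 2),
      count = c(fields[[1]], fields[[2]]))
    list(distribution = dist_tab, comparison = cmp)
  })

  panels <- stage("nucleotides", {
    simulate_cohort_panels(profiles, seed = seed + 500)
  })
  nuc_cor <- stage("nucleotide-correlations", {
    correlate_tdgv_nucleotides(panels[panels$group == "control", ,
                                      drop = FALSE])
  })

  stage("write", {
    jsonlite::write_json(profiles, file.path(out_dir, "profiles.json"),
                         dataframe = "rows", digits = NA)
    utils::write.csv(cls$labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ranges, file.path(out_dir, "reference.json"),
                         dataframe = "rows", digits = NA)
    sep <- profiles[, c("patient_id", "group", "dg_per_platelet",
                        "tdgv_nm3")]
    sep$category <- cls$labels$category
    utils::write.csv(sep, file.path(out_dir, "tdgv_separation.csv"),
                     row.names = FALSE)
    utils::write.csv(ur$distribution,
                     file.path(out_dir, "uranaffin_distribution.csv"),
                     row.names = FALSE)
    cors <- rbind(
      data.frame(pair = "dg_per_platelet~tdgv", n = cvc$n, r = cvc$r,
                 p_value = cvc$p_value),
      data.frame(pair = paste0("tdgv~", nuc_cor$variable), n = nuc_cor$n,
                 r = nuc_cor$r, p_value = nuc_cor$p_value))
    utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    cfg_file <- file.path(out_dir, "config_used.yaml")
    yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_file)
    log_lines <- c(
      paste("seed:", seed),
      paste("config_sha:", unname(tools::md5sum(cfg_file))),
      paste("r_version:", R.version.string),
      paste("granulovol:",
            as.character(utils::packageVersion("granulovol"))),
      paste("groups:", paste(groups, collapse = ", ")),
      paste("source:", config$source))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  })

  invisible(list(profiles = profiles, ranges = ranges,
                 classification = cls, group_summary = summary_tab,
                 count_volume = cvc, uranaffin = ur,
                 panels = panels, nucleotide_correlations = nuc_cor))
}
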