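# Study orchestration and group statistics.

#' One-way ANOVA with Tukey post hoc comparisons
#'
#' Group means are compared by one-way analysis of variance followed by
#' Tukey's honestly-significant-difference test for all pairwise contrasts;
#' significance is flagged at `alpha` (default 0.05).
#'
#' @param values numeric response vector.
#' @param group group label per value (>= 2 groups, each with >= 2 values).
#' @param alpha significance level.
#' @return object of class `group_comparison`: `groups` (per-group n, mean,
#'   sd), `f_statistic`, `p_value`, `pairwise` (one row per unordered pair
#'   with the Tukey-adjusted p and a significance flag), `alpha`.
#' @examples
#' compare_groups(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  keep <- is.finite(values)
  values <- values[keep]; group <- as.character(group)[keep]
  counts <- table(group)
  if (length(counts) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L))
    stop("insufficient replicates: group(s) ",
         paste(names(counts)[counts < 2L], collapse = ", "),
         " have fewer than 2 values", call. = FALSE)
  df <- data.frame(value = values, group = factor(group))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pair_names <- rownames(tk)
  pairwise <- data.frame(
    pair = pair_names,
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL
  )
  per_group <- data.frame(
    group = names(counts),
    n = as.integer(counts),
    mean = as.numeric(tapply(values, group, mean)),
    sd = as.numeric(tapply(values, group, stats::sd))
  )
  structure(list(groups = per_group,
                 f_statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 pairwise = pairwise,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (alpha = %g)\n",
              x$f_statistic, x$p_value, x$alpha))
  print(x$groups, row.names = FALSE)
  cat("Tukey HSD:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Run the full biofilm-mechanics pipeline
#'
#' Analyses every record of a study — rotating-disc detachment metrics per
#' torque curve, thickness and Young's modulus per indentation, biomass and
#' roughness per image stack — then compares treatment groups per metric
#' (one-way ANOVA + Tukey) and computes the replicate-level zinc-arginine
#' interaction index. Technical replicates are averaged to one value per
#' biological replicate before the group statistics (the biological replicate
#' is the experimental unit); set `average_technical = FALSE` to treat every
#' record as independent.
#'
#' Per-record failures never abort the run: the record is logged and skipped,
#' and the run is flagged `partial`.
#'
#' @param study a `synthetic_study` from [generate_study()], or a directory
#'   written by [write_study()] (the manifest is read back).
#' @param out_dir optional directory; when given, tidy CSV reports are
#'   written (`rheometry.csv`, `indentation.csv`, `imaging.csv`, one
#'   `comparison_<metric>.csv` per metric, `interaction.csv`).
#' @param alpha significance level for group comparisons.
#' @param average_technical average technical replicates per biological
#'   replicate before ANOVA.
#' @param geometry,fluid,probe instrument models used in the analysis.
#' @return object of class `pipeline_report`: per-record metric tables
#'   (`rheometry`, `indentation`, `imaging`), `comparisons` (named list of
#'   [compare_groups()] results), `interaction` (replicate interaction-index
#'   summary or the error message), `status` (`"clean"` or `"partial"`) and
#'   `failures`.
#' @export
run_pipeline <- function(study, out_dir = NULL, alpha = 0.05,
                         average_technical = TRUE,
                         geometry = disc_geometry(),
                         fluid = fluid_properties(),
                         probe = probe_geometry()) {
  if (is.character(study)) study <- read_study(study)
  failures <- list()
  note_failure <- function(id, stage, e) {
    failures[[length(failures) + 1L]] <<-
      data.frame(id = id, stage = stage, error = conditionMessage(e))
    log_event("[", stage, "] ", id, " failed: ", conditionMessage(e))
  }
  meta_of <- function(id) {
    row <- study$manifest[study$manifest$id == id, , drop = FALSE]
    list(group = row$group[1], biological = row$biological[1])
  }

  rheo <- list()
  for (id in names(study$torque)) {
    m <- meta_of(id)
    tryCatch({
      fit <- rheology_fit(study$torque[[id]]$curve, geometry, fluid)
      rheo[[id]] <- data.frame(id = id, group = m$group,
                               biological = m$biological,
                               cf = fit$cf, auc = fit$auc,
                               tau_star = fit$tau_star,
                               n_events = nrow(fit$events))
    }, error = function(e) note_failure(id, "rheometry", e))
  }
  rheo <- if (length(rheo)) do.call(rbind, rheo) else NULL

  indent <- list()
  for (id in names(study$indentation)) {
    m <- meta_of(id)
    tryCatch({
      fit <- indentation_fit(study$indentation[[id]]$curve, probe)
      indent[[id]] <- data.frame(id = id, group = m$group,
                                 biological = m$biological,
                                 delta_c = fit$contact$delta_c,
                                 thickness = fit$contact$h,
                                 slope = fit$slope,
                                 r_squared = fit$r_squared, E = fit$E)
    }, error = function(e) note_failure(id, "indentation", e))
  }
  indent <- if (length(indent)) do.call(rbind, indent) else NULL

  imaging <- list()
  for (id in names(study$images)) {
    m <- meta_of(id)
    tryCatch({
      q <- quantify_stack(study$images[[id]]$stack)
      q$id <- id; q$group <- m$group; q$biological <- m$biological
      imaging[[id]] <- q
    }, error = function(e) note_failure(id, "imaging", e))
  }
  imaging <- if (length(imaging)) do.call(rbind, imaging) else NULL

  unit_values <- function(df, col) {
    # collapse to one value per biological replicate when requested
    if (is.null(df)) return(NULL)
    ok <- is.finite(df[[col]])
    df <- df[ok, , drop = FALSE]
    if (nrow(df) == 0L) return(NULL)
    if (average_technical) {
      key <- interaction(df$group, df$biological, drop = TRUE)
      data.frame(value = as.numeric(tapply(df[[col]], key, mean)),
                 group = as.character(tapply(df$group, key, `[`, 1L)))
    } else {
      data.frame(value = df[[col]], group = df$group)
    }
  }

  metric_sources <- list(
    cf = list(rheo, "cf"), auc = list(rheo, "auc"),
    tau_star = list(rheo, "tau_star"),
    thickness = list(indent, "thickness"), E = list(indent, "E"),
    biomass_cells = list(
      if (!is.null(imaging)) imaging[imaging$channel == "cells", ], "biomass"),
    biomass_eps = list(
      if (!is.null(imaging)) imaging[imaging$channel == "eps", ], "biomass"),
    roughness_eps = list(
      if (!is.null(imaging)) imaging[imaging$channel == "eps", ], "roughness")
  )
  comparisons <- list()
  for (metric in names(metric_sources)) {
    src <- metric_sources[[metric]]
    uv <- unit_values(src[[1]], src[[2]])
    if (is.null(uv)) next
    comparisons[[metric]] <- tryCatch(
      compare_groups(uv$value, uv$group, alpha = alpha),
      error = function(e) { note_failure(metric, "compare_groups", e); NULL })
  }
  comparisons <- Filter(Negate(is.null), comparisons)

  iai_summary <- NULL
  if (!is.null(indent)) {
    # biological-replicate moduli feed the interaction index
    iai_summary <- tryCatch({
      key <- interaction(indent$group, indent$biological, drop = TRUE)
      tab <- modulus_table(
        group = as.character(tapply(indent$group, key, `[`, 1L)),
        replicate = as.integer(tapply(indent$biological, key, `[`, 1L)),
        E = as.numeric(tapply(indent$E, key, mean)))
      replicate_interaction_summary(tab, pairing = "matched")
    }, error = function(e) {
      note_failure("interaction_index", "interaction", e)
      conditionMessage(e)
    })
  }

  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  report <- structure(list(rheometry = rheo, indentation = indent,
                           imaging = imaging, comparisons = comparisons,
                           interaction = iai_summary,
                           status = if (is.null(failures)) "clean" else "partial",
                           failures = failures,
                           alpha = alpha),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (", x$status, ")\n", sep = "")
  for (tab in c("rheometry", "indentation", "imaging"))
    if (!is.null(x[[tab]]))
      cat(sprintf("  %s: %d record(s)\n", tab, nrow(x[[tab]])))
  for (metric in names(x$comparisons)) {
    cmp <- x$comparisons[[metric]]
    cat(sprintf("  %s: F = %.4g, p = %.4g\n", metric,
                cmp$f_statistic, cmp$p_value))
  }
  if (is.list(x$interaction))
    cat(sprintf("  interaction index: %.4g +/- %.4g (%s)\n",
                x$interaction$mean, x$interaction$sd,
                x$interaction$classification))
  if (!is.null(x$failures))
    cat("  failures:", nrow(x$failures), "(see $failures)\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(report$rheometry, "rheometry.csv")
  w(report$indentation, "indentation.csv")
  w(report$imaging, "imaging.csv")
  for (metric in names(report$comparisons)) {
    cmp <- report$comparisons[[metric]]
    w(cbind(metric = metric, cmp$pairwise,
            f_statistic = cmp$f_statistic, p_value = cmp$p_value),
      paste0("comparison_", metric, ".csv"))
  }
  if (is.list(report$interaction)) {
    w(data.frame(mean = report$interaction$mean, sd = report$interaction$sd,
                 classification = report$interaction$classification,
                 pairing = report$interaction$pairing,
                 n = length(report$interaction$values)),
      "interaction.csv")
  }
  w(report$failures, "failures.csv")
  invisible(out_dir)
}

#' Read a study directory back into memory
#'
#' Reads the manifest written by [write_study()] and loads each record with
#' the package readers, so a materialised study can be piped through
#' [run_pipeline()] exactly like an in-memory one.
#'
#' @param dir study directory containing `manifest.csv`.
#' @return a `synthetic_study`-shaped list (without truth sidecars).
#' @export
read_study <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path))
    stop("no manifest.csv in '", dir, "'", call. = FALSE)
  manifest <- utils::read.csv(mf_path)
  torque <- list(); indentation <- list(); images <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]; kind <- manifest$kind[i]
    files <- strsplit(manifest$file[i], ";", fixed = TRUE)[[1]]
    paths <- file.path(dir, files)
    if (kind == "torque") {
      torque[[id]] <- list(curve = read_rheometry_csv(
        paths[1], treatment = manifest$group[i], coupon_id = id))
    } else if (kind == "indentation") {
      indentation[[id]] <- list(curve = read_indentation_csv(
        paths[1], treatment = manifest$group[i], disc_id = id))
    } else if (kind == "image") {
      names(paths) <- c("cells", "eps")
      vx <- c(manifest$voxel_dz[i], manifest$voxel_dy[i], manifest$voxel_dx[i])
      stk <- read_image_stack(paths, voxel_size = vx)
      # stored as 0/1 8-bit; recover logical channels
      stk$channels <- lapply(stk$channels, function(a) a > 0.5)
      images[[id]] <- list(stack = stk)
    }
  }
  structure(list(torque = torque, indentation = indentation, images = images,
                 manifest = manifest, spec = NULL),
            class = "synthetic_study")
}
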