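#' Full study-replica pipeline
#'
#' Orchestrates simulate -> element-wise GLM + TFCE permutation inference
#' -> parcel-level FDR tests and network summaries -> structural covariance
#' seed maps -> concordance with functional network templates, with one
#' global seed from which every stage derives its own seed by fixed
#' offsets. The demo scale defaults (mesh level 3, 50 parcels, 500
#' permutations) are a scaled-down stand-in for a full-resolution run.
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' @param mesh_level icosphere subdivision level for the surface domain.
#' @param n_parcels number of parcels K.
#' @param sim a [simulation_config()].
#' @param tfce a [tfce_params()].
#' @param n_perm permutations for FWE inference.
#' @param alphas thresholds: `fwe_vertex` (element-wise FWE, default
#'   0.001), `fdr_roi` (parcel FDR q, default 0.01), `cov_alpha` (seed-map
#'   correlation test, default 0.05), `fwe_behav` (behavioral regression
#'   FWE, default 0.05).
#' @param r_min functional template threshold (default 0.2, strict `>`).
#' @param n_seeds seed parcels per group for covariance maps (default 2).
#' @param functional_level within-network level of the functional
#'   templates.
#' @param stages named logical toggles: `infer`, `roi`, `covariance`,
#'   `concordance`.
#' @param rng_seed global seed; stage seeds are `rng_seed + offset` with
#'   fixed documented offsets (parcellation +11, cohort +23, templates
#'   +77, inference +100 + contrast index).
#' @param out_dir optional directory for TSV/JSON stage outputs.
#' @return A `ctcov_run_config` list.
#' @export
pipeline_config <- function(mesh_level = 3, n_parcels = 50,
                            sim = simulation_config(),
                            tfce = tfce_params(),
                            n_perm = 500,
                            alphas = list(fwe_vertex = 0.001,
                                          fdr_roi = 0.01,
                                          cov_alpha = 0.05,
                                          fwe_behav = 0.05),
                            r_min = 0.2, n_seeds = 2,
                            functional_level = 0.6,
                            stages = list(infer = TRUE, roi = TRUE,
                                          covariance = TRUE,
                                          concordance = TRUE),
                            rng_seed = 1, out_dir = NULL) {
  stopifnot(all(unlist(alphas) > 0), all(unlist(alphas) < 1))
  structure(list(mesh_level = mesh_level, n_parcels = n_parcels,
                 sim = sim, tfce = tfce, n_perm = n_perm, alphas = alphas,
                 r_min = r_min, n_seeds = n_seeds,
                 functional_level = functional_level, stages = stages,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "ctcov_run_config")
}

# polynomial rolling hash of a config's JSON serialization (provenance tag)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config)[setdiff(names(config), "out_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

group_contrast_pairs <- function(groups) {
  pairs <- list()
  for (i in seq_along(groups))
    for (j in seq_along(groups))
      if (i < j) pairs[[length(pairs) + 1L]] <- c(groups[i], groups[j])
  pairs
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return A `ctcov_run_report` list with per-stage results and a
#'   `provenance` entry (seed, config hash, stage seeds). Deterministic
#'   given the config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ctcov_run_config"))
  seed <- config$rng_seed
  prov <- list(rng_seed = seed, config_hash = config_hash(config),
               stage_seeds = list(parcellation = seed + 11L,
                                  cohort = seed + 23L,
                                  templates = seed + 77L,
                                  inference_base = seed + 100L))
  domain <- build_mesh_domain(config$mesh_level)
  parcellation <- make_parcellation(domain, config$n_parcels,
                                    rng_seed = seed + 11L)
  cohort <- simulate_cohort(config$sim, domain, parcellation,
                            rng_seed = seed + 23L)
  groups <- names(config$sim$group_sizes)
  report <- list(provenance = prov,
                 domain = list(mode = domain$mode,
                               n_elements = domain$n_elements,
                               n_parcels = config$n_parcels),
                 groups = as.list(config$sim$group_sizes))

  pairs <- group_contrast_pairs(groups)
  contrasts <- list()
  for (pr in pairs) {
    cname <- paste(pr, collapse = "_vs_")
    cv <- stats::setNames(c(1, -1), pr)
    design <- make_design(cohort$covariates, cv, covariate_names = "age",
                          groups = groups)
    stat <- fit_contrast(cohort, design)
    entry <- list(stage = "glm", contrast = cname, dof = stat$dof,
                  max_t = max(stat$t), min_t = min(stat$t))
    if (isTRUE(config$stages$infer)) {
      inf <- permutation_fwe(cohort, design, domain, config$tfce,
                             n_perm = config$n_perm,
                             alpha = config$alphas$fwe_vertex,
                             rng_seed = seed + 100L + length(contrasts),
                             tail = "pos")
      entry$n_significant <- sum(inf$sig_mask)
      entry$min_p_fwe <- min(inf$p_fwe)
      entry$inference <- inf
    }
    entry$design <- design
    contrasts[[cname]] <- entry
  }
  report$contrasts <- lapply(contrasts, function(e)
    e[setdiff(names(e), c("inference", "design"))])

  sud_groups <- setdiff(groups, "CON")
  if (isTRUE(config$stages$roi) && "CON" %in% groups) {
    pm <- parcel_means(cohort, parcellation)
    roi <- list()
    for (g in sud_groups) {
      design <- make_design(cohort$covariates,
                            stats::setNames(c(1, -1), c("CON", g)),
                            covariate_names = "age", groups = groups)
      rt <- roi_group_test(pm, design, q = config$alphas$fdr_roi)
      sig_ids <- pm$parcels$parcel_id[rt$mask]
      ns <- network_summary(sig_ids, parcellation)
      roi[[g]] <- list(stage = "roi", n_significant = length(sig_ids),
                       significant_parcels = as.integer(sig_ids),
                       by_family = ns$by_family)
    }
    report$roi <- roi
  }

  if (isTRUE(config$stages$covariance) && "CON" %in% groups) {
    pm_all <- parcel_means(cohort, parcellation)
    covres <- list()
    for (g in sud_groups) {
      sel <- cohort$covariates$group == g
      pm_g <- pm_all
      pm_g$values <- pm_g$values[sel, , drop = FALSE]
      pm_g <- center_subjects(pm_g)
      pm_g <- age_residualize(pm_g, cohort$covariates$age[sel])
      cv <- covariance_matrix(pm_g, group = g)
      cname <- paste0("CON_vs_", g)
      seeds <- NULL
      if (!is.null(contrasts[[cname]]$inference) &&
          any(contrasts[[cname]]$inference$sig_mask)) {
        seeds <- peak_seed(contrasts[[cname]]$inference, domain,
                           parcellation, n_seeds = config$n_seeds)
      } else {
        # fall back to the parcels with the largest parcel-level deficit
        design <- make_design(cohort$covariates,
                              stats::setNames(c(1, -1), c("CON", g)),
                              covariate_names = "age", groups = groups)
        rt <- roi_group_test(pm_all, design, q = config$alphas$fdr_roi)
        seeds <- pm_all$parcels$parcel_id[order(-rt$t)][
          seq_len(config$n_seeds)]
      }
      maps <- lapply(seeds, function(s)
        seed_map(cv, s, alpha = config$alphas$cov_alpha))
      covres[[g]] <- list(stage = "covariance", seeds = as.integer(seeds),
                          n_subjects = cv$n_subjects,
                          members = lapply(maps, function(m)
                            as.integer(m$members)),
                          maps = maps)
    }
    report$covariance <- lapply(covres, function(e)
      e[setdiff(names(e), "maps")])

    if (isTRUE(config$stages$concordance)) {
      templates <- simulate_functional_templates(
        domain, parcellation, within_network_level = config$functional_level,
        rng_seed = seed + 77L)
      conc <- list()
      for (g in sud_groups) {
        e <- covres[[g]]
        # render: union of seed maps, seeds included
        pids <- unique(c(e$seeds, unlist(e$members)))
        cov_map <- parcels_to_map(pids, parcellation)
        fam <- parcellation$parcels$network_family[
          match(e$seeds[1], parcellation$parcels$parcel_id)]
        func_map <- threshold_map(templates[[fam]], config$r_min)
        ov <- overlap(cov_map, func_map, reference = "smaller")
        conc[[g]] <- list(stage = "concordance", seed_family = fam,
                          overlap_pct = ov$overlap_pct, dice = ov$dice,
                          size_covariance = ov$size_a,
                          size_functional = ov$size_b,
                          size_intersection = ov$size_intersection)
      }
      report$concordance <- conc
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  structure(report, class = "ctcov_run_report")
}

#' @export
print.ctcov_run_report <- function(x, ...) {
  cat("<ctcov_run_report>\n")
  for (cn in names(x$contrasts)) {
    e <- x$contrasts[[cn]]
    cat(sprintf("  %-12s max t = %6.2f%s\n", cn, e$max_t,
                if (!is.null(e$n_significant))
                  sprintf(", %d significant elements", e$n_significant)
                else ""))
  }
  for (g in names(x$roi))
    cat(sprintf("  ROI %s: %d significant parcels\n", g,
                x$roi[[g]]$n_significant))
  for (g in names(x$concordance))
    cat(sprintf("  concordance %s (%s): %.1f%%\n", g,
                x$concordance[[g]]$seed_family,
                x$concordance[[g]]$overlap_pct))
  invisible(x)
}
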