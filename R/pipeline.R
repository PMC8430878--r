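#' Build and validate a pipeline run configuration
#'
#' Nested named lists configure each stage; unknown keys at any level are
#' rejected so that typos never silently fall back to defaults. Physical
#' overrides use the same units as [tissue_constants()] (SI) and
#' [phantom_spec()] (mm, s, 1/min).
#'
#' @param stages Character vector, subset of
#'   c("simulate", "fit", "domain", "solve", "stats"), or "all".
#' @param out_dir Artifact directory.
#' @param seed Integer seed for every stochastic stage.
#' @param cohort Overrides for [cohort_spec()].
#' @param fit List: `baseline_frames`, `relaxivity`, `multi_start`.
#' @param domain List: `dilation_voxels`, `new_spacing`.
#' @param solver List: `tol`, `scaling_mode`.
#' @param constants Overrides for [tissue_constants()].
#' @return A `run_config` list.
#' @export
run_config <- function(stages = "all", out_dir = tempfile("dceflow_run_"),
                       seed = 1L, cohort = list(), fit = list(),
                       domain = list(), solver = list(), constants = list()) {
  all_stages <- c("simulate", "fit", "domain", "solve", "stats")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown ", where, " key(s): ",
                          paste(bad, collapse = ", "))
    x
  }
  cohort <- check_keys(cohort, names(formals(cohort_spec)), "cohort")
  fit_def <- list(baseline_frames = 3L, relaxivity = 4.5, multi_start = FALSE)
  fit <- utils::modifyList(fit_def, check_keys(fit, names(fit_def), "fit"))
  dom_def <- list(dilation_voxels = 10, new_spacing = 1)
  domain <- utils::modifyList(dom_def, check_keys(domain, names(dom_def),
                                                  "domain"))
  sol_def <- list(tol = 1e-10, scaling_mode = "ktrans_scaling")
  solver <- utils::modifyList(sol_def, check_keys(solver, names(sol_def),
                                                  "solver"))
  constants <- check_keys(constants, names(tissue_constants()), "constants")
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, fit = fit, domain = domain, solver = solver,
                 constants = constants),
            class = "run_config")
}

.write_map <- function(img, spacing, path) {
  im <- RNifti::asNifti(img * 1)
  im <- RNifti::`pixdim<-`(im, rep_len(spacing, length(dim(img))))
  RNifti::writeNifti(im, path)
  path
}

#' Write parametric maps as NIfTI with a units sidecar
#'
#' @param maps Named list of 3D arrays.
#' @param units Named character vector of units per map.
#' @param dir Output directory. @param prefix File prefix.
#' @param spacing Voxel spacing, mm.
#' @return Invisibly, the vector of written paths.
#' @export
write_parametric_maps <- function(maps, units, dir, prefix, spacing) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(maps), function(nm) {
    m <- maps[[nm]]
    m[is.na(m)] <- 0
    .write_map(m, spacing, file.path(dir, paste0(prefix, "_", nm, ".nii.gz")))
  }, "")
  jsonlite::write_json(as.list(units[names(maps)]),
                       file.path(dir, paste0(prefix, "_units.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a DCE exam from NIfTI files
#'
#' Loads the 4D dynamic series, T10 map and tumor mask (plus the time axis
#' and acquisition metadata from the JSON sidecar, when present) into plain
#' arrays after validating the headers with [validate_inputs()].
#'
#' @param paths Named list/vector with `series`, `t10`, `mask` and
#'   optionally `provenance` (JSON sidecar).
#' @return List: `signal` (4D array), `t10`, `mask` (3D arrays), `spacing`
#'   (mm, from the series header), `times` (s, or NULL), `meta` (sidecar
#'   contents, or NULL).
#' @export
read_dce_inputs <- function(paths) {
  rep <- validate_inputs(paths)
  if (!rep$ok) stop("invalid inputs: ", paste(rep$errors, collapse = "; "))
  paths <- as.list(paths)
  series <- RNifti::readNifti(paths$series)
  spacing <- RNifti::pixdim(series)[1:3]
  meta <- NULL
  times <- NULL
  if (!is.null(paths$provenance)) {
    meta <- jsonlite::read_json(paths$provenance, simplifyVector = TRUE)
    times <- meta$times_s
  }
  list(signal = as.array(series),
       t10 = as.array(RNifti::readNifti(paths$t10)),
       mask = as.array(RNifti::readNifti(paths$mask)) != 0,
       spacing = spacing, times = times, meta = meta)
}

#' Validate pipeline input files
#'
#' Header-level checks on a named set of paths (`series`, `t10`, `mask`,
#' optionally `provenance` for the time axis): readability (fatal), grid
#' alignment between series/T10/mask (fatal), empty mask (fatal),
#' non-monotone time metadata (fatal). Non-fatal issues are listed as
#' warnings.
#'
#' @param paths Named character vector or list of file paths.
#' @return List with `errors`, `warnings`, and `ok` (no fatal errors).
#' @export
validate_inputs <- function(paths) {
  errors <- character(); warnings <- character()
  paths <- as.list(paths)
  imgs <- list()
  for (nm in intersect(c("series", "t10", "mask"), names(paths))) {
    p <- paths[[nm]]
    if (!file.exists(p)) {
      errors <- c(errors, paste0(nm, ": file not found: ", p)); next
    }
    imgs[[nm]] <- tryCatch(RNifti::readNifti(p), error = function(e) {
      errors <<- c(errors, paste0(nm, ": unreadable NIfTI: ", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(imgs$series)) {
    if (length(dim(imgs$series)) != 4L)
      errors <- c(errors, "series: expected a 4D dynamic series")
    for (nm in c("t10", "mask")) {
      if (!is.null(imgs[[nm]]) &&
          !identical(dim(imgs[[nm]])[1:3], dim(imgs$series)[1:3]))
        errors <- c(errors, paste0(nm, ": grid does not match the series grid"))
    }
  }
  if (!is.null(imgs$mask) && !any(imgs$mask != 0))
    errors <- c(errors, "mask: empty tumor mask")
  if (!is.null(paths$provenance)) {
    if (!file.exists(paths$provenance)) {
      errors <- c(errors, "provenance: file not found")
    } else {
      meta <- tryCatch(jsonlite::read_json(paths$provenance,
                                           simplifyVector = TRUE),
                       error = function(e) NULL)
      if (is.null(meta) || is.null(meta$times_s)) {
        warnings <- c(warnings, "provenance: no time axis recorded")
      } else if (any(diff(meta$times_s) <= 0)) {
        errors <- c(errors, "provenance: non-monotone time axis")
      }
    }
  }
  list(errors = errors, warnings = warnings, ok = length(errors) == 0L)
}

# fit all kinetic stages for one phantom dataset; returns maps + fits
.fit_dataset <- function(ds, fit_cfg, constants) {
  cv <- concentration_from_signal(ds$signal, ds$t10,
                                  tr = ds$provenance$spec$tr,
                                  fa = ds$provenance$spec$fa,
                                  relaxivity = fit_cfg$relaxivity,
                                  baseline_frames = fit_cfg$baseline_frames)
  etm <- fit_etm_map(cv$conc, ds$mask, ds$aif, ds$times,
                     multi_start = fit_cfg$multi_start)
  cp <- ds$aif$cp
  idx <- which(ds$mask)
  cmat <- matrix(cv$conc, ncol = length(ds$times))[idx, , drop = FALSE]
  jvv <- array(NA_real_, dim(ds$mask))
  psv <- array(NA_real_, dim(ds$mask))
  sig_t <- constants$sigma_t[["tumor"]]
  for (i in seq_along(idx)) {
    ve_i <- etm$ve[idx[i]]; vp_i <- etm$vp[idx[i]]
    if (!is.finite(ve_i) || ve_i <= 0) next
    ce <- derive_ce(cmat[i, ], cp, ve_i, vp_i)$ce
    fx <- fit_flux_model(ce, cp, ds$times, sigma_t = sig_t, ve = ve_i)
    jvv[idx[i]] <- fx$jvv; psv[idx[i]] <- fx$psv
  }
  lp <- tryCatch(rescale_lp(ifelse(is.na(jvv), 0, jvv), ds$mask),
                 error = function(e) NULL)
  list(conc = cv$conc, etm = etm, jvv = jvv, psv = psv, lp = lp)
}

#' Run the modeling pipeline end to end on a synthetic cohort
#'
#' Executes the selected stages in order — phantom synthesis, signal-to-
#' concentration conversion and kinetic/flux fitting, domain construction,
#' pressure/velocity simulation, cohort statistics — writing every
#' intermediate artifact (NIfTI maps, CSV tables, Markdown report) plus a
#' JSON manifest carrying the seed, configuration and its hash. A stage
#' failure halts the run with the stage name.
#'
#' @param config A [run_config()].
#' @return The artifact directory path, invisibly; the manifest lists every
#'   written file.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  constants <- do.call(tissue_constants, config$constants)
  artifacts <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- stage("simulate", {
      cs <- do.call(cohort_spec, utils::modifyList(list(seed = config$seed),
                                                   config$cohort))
      co <- generate_cohort(cs)
      for (s in seq_along(co$subjects)) {
        for (tp in seq_along(co$timepoints)) {
          ds <- co$subjects[[s]]$datasets[[tp]]
          if (is.null(ds)) next
          pd <- file.path(config$out_dir, sprintf("sub%02d", s))
          pr <- sprintf("tp%d", tp)
          artifacts <- c(artifacts, write_phantom(ds, pd, pr))
        }
      }
      co
    })
  }
  summaries <- NULL
  if (all(c("fit", "domain", "solve") %in% config$stages) &&
      !is.null(cohort)) {
    rows <- list()
    for (s in seq_along(cohort$subjects)) {
      for (tp in seq_along(cohort$timepoints)) {
        ds <- cohort$subjects[[s]]$datasets[[tp]]
        if (is.null(ds)) next
        fitted <- stage("fit", .fit_dataset(ds, config$fit, constants))
        sp <- ds$provenance$spec$spacing
        dom <- stage("domain", {
          d <- build_domain(ds$mask, sp, fitted$etm$ktrans,
                            dilation_voxels = config$domain$dilation_voxels,
                            new_spacing = config$domain$new_spacing)
          if (!is.null(fitted$lp) &&
              config$solver$scaling_mode %in% c("lp_field", "both")) {
            lp_iso <- resample_iso(ifelse(is.na(fitted$lp$lp_sv), 0,
                                          fitted$lp$lp_sv),
                                   sp, config$domain$new_spacing, "trilinear")
            d$lp_sv <- array(NA_real_, dim(d$labels))
            d$lp_sv[d$labels == 2L] <- lp_iso[d$labels == 2L]
          }
          d
        })
        pf <- stage("solve", solve_ifp(dom, constants,
                                       config$solver$scaling_mode,
                                       config$solver$tol))
        vf <- compute_ifv(pf)
        pd <- file.path(config$out_dir, sprintf("sub%02d", s))
        artifacts <- c(artifacts, write_parametric_maps(
          list(ktrans = fitted$etm$ktrans, ve = fitted$etm$ve,
               vp = fitted$etm$vp, jvv = fitted$jvv),
          c(ktrans = "1/min", ve = "fraction", vp = "fraction", jvv = "1/s"),
          pd, sprintf("tp%d_maps", tp), sp))
        artifacts <- c(artifacts, write_parametric_maps(
          list(ifp_kpa = pf$p / 1000, ifv_ms = vf$magnitude,
               ux = vf$ux, uy = vf$uy, uz = vf$uz, labels = dom$labels),
          c(ifp_kpa = "kPa", ifv_ms = "m/s", ux = "m/s", uy = "m/s",
            uz = "m/s", labels = "label"),
          pd, sprintf("tp%d_cfm", tp), config$domain$new_spacing))
        diag_path <- file.path(pd, sprintf("tp%d_solver_diagnostics.json", tp))
        jsonlite::write_json(pf$diagnostics, diag_path, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        artifacts <- c(artifacts, diag_path)
        rows[[length(rows) + 1L]] <-
          summarize_fields(pf, vf, dom, cohort$timepoints[tp],
                           subject = sprintf("sub%02d", s))
      }
    }
    summaries <- do.call(rbind, rows)
    sp_path <- file.path(config$out_dir, "timepoint_summaries.csv")
    utils::write.csv(summaries, sp_path, row.names = FALSE)
    artifacts <- c(artifacts, sp_path)
  }
  if ("stats" %in% config$stages && !is.null(summaries)) {
    st <- stage("stats", cohort_table(summaries))
    rp <- file.path(config$out_dir, "cohort_report.md")
    writeLines(st$report, rp)
    bt <- file.path(config$out_dir, "cohort_by_timepoint.csv")
    utils::write.csv(st$by_timepoint, bt, row.names = FALSE)
    artifacts <- c(artifacts, rp, bt)
    if (!is.null(st$wilcoxon)) {
      wp <- file.path(config$out_dir, "cohort_wilcoxon.csv")
      utils::write.csv(st$wilcoxon, wp, row.names = FALSE)
      artifacts <- c(artifacts, wp)
    }
    if (!is.null(st$spearman)) {
      cp <- file.path(config$out_dir, "cohort_spearman.csv")
      utils::write.csv(st$spearman, cp, row.names = FALSE)
      artifacts <- c(artifacts, cp)
    }
  }
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  # hash the run identity (everything but the artifact location)
  hashable <- unclass(config); hashable$out_dir <- NULL
  hp <- tempfile(fileext = ".json")
  jsonlite::write_json(hashable, hp, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(hp)),
                   package_version = as.character(utils::packageVersion("dceflow")),
                   constants = lapply(unclass(constants), as.list),
                   stages = config$stages,
                   artifacts = basename(unname(artifacts)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
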