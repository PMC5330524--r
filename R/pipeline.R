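# Study orchestration: reference generation -> amplitude sets -> lambda /
# resolution scans -> similarity metrics -> report tables.  Everything is
# deterministic given the configuration; intermediate artifacts are cached
# in-memory per run and optionally on disk keyed by their defining
# parameters, so interrupted studies resume without recomputation.

#' Study configuration
#'
#' Bundles every setting of a constrained-wavefunction study.  The defaults
#' are the package's production-analog conditions: a 10 angstrom cubic P1
#' cell, the full resolution ladder sin(theta)/lambda <=
#' {0.25, 0.5, 0.7, 0.9, 1.2, 1.5, 2.0} 1/angstrom, the lambda grid 0 to 10
#' in steps of 0.5, sigma = eta = 1, and a CISD correlated reference.
#'
#' @param molecules character vector of fixture names (see
#'   [fixture_geometry()]).
#' @param basis basis-set name.
#' @param cell an [unit_cell()].
#' @param s_max_list resolution cutoffs, 1/angstrom.
#' @param lambdas constraint-weight grid (ascending, starting at 0).
#' @param reference correlated reference method (`"CISD"` or `"FCI"`).
#' @param grid_spacing metric-grid spacing, bohr.
#' @param friedel Friedel policy for generated reflection sets.
#' @param with_fields if TRUE also compute RSR/Carbo/RMSD/MAD fields per
#'   lambda point (slower); TI tables are always computed.
#' @param cache_dir optional directory for on-disk caching of stage
#'   results.
#' @param seed recorded for provenance; no stage of the pipeline is
#'   stochastic, so it is never consumed.
#' @return A list of class `xcw_study_config`.
#' @export
study_config <- function(molecules = c("N2", "CN-", "water"),
                         basis = "6-31gdp",
                         cell = unit_cell(10),
                         s_max_list = c(0.25, 0.5, 0.7, 0.9, 1.2, 1.5, 2.0),
                         lambdas = seq(0, 10, by = 0.5),
                         reference = "CISD",
                         grid_spacing = 0.15,
                         friedel = "unique-hemisphere",
                         with_fields = FALSE,
                         cache_dir = NULL,
                         seed = NULL) {
  structure(list(molecules = molecules, basis = basis, cell = cell,
                 s_max_list = s_max_list, lambdas = lambdas,
                 reference = reference, grid_spacing = grid_spacing,
                 friedel = friedel, with_fields = with_fields,
                 cache_dir = cache_dir, seed = seed),
            class = "xcw_study_config")
}

config_key <- function(...) {
  paste(vapply(list(...), function(x) paste(format(x, digits = 12), collapse = "_"), ""),
        collapse = "__")
}

cache_get <- function(dir, key, compute) {
  if (is.null(dir)) return(compute())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "-", key), ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Run a constrained-wavefunction study
#'
#' For each molecule: pinned geometry, RHF and correlated reference
#' densities, per-resolution reflection sets with reference amplitudes,
#' warm-started lambda scans, and the TI of the constrained density at each
#' named bond critical point (plus field-based indicators when
#' `with_fields` is set).  Non-converged points are kept in the tables but
#' flagged, never imputed.
#'
#' @param config an [study_config()].
#' @param verbose print stage progress.
#' @return Object of class `xcw_study`: per-molecule result lists plus the
#'   configuration.
#' @export
run_study <- function(config = study_config(), verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list()
  for (mname in config$molecules) {
    say("== %s ==", mname)
    mol <- fixture_geometry(mname)
    bonds <- fixture_bonds(mname)
    ints <- cache_get(config$cache_dir, config_key("ints", mname, config$basis),
                      function() compute_integrals(mol, config$basis))
    d_rhf <- rhf_density(mol, config$basis, ints = ints)
    d_corr <- cache_get(config$cache_dir,
                        config_key("ref", mname, config$basis, config$reference),
                        function() correlated_density(mol, config$basis,
                                                      config$reference, ints = ints))
    say("  %s reference: E = %.6f (corr %.6f)", config$reference,
        d_corr$energy, d_corr$energy - d_rhf$energy)
    bcp_rhf <- lapply(bonds, function(b) find_bcp(d_rhf, b[1], b[2]))
    bcp_corr <- lapply(bonds, function(b) find_bcp(d_corr, b[1], b[2]))
    grid <- if (config$with_fields) default_grid(mol, config$grid_spacing) else NULL
    f_corr <- if (config$with_fields) density_on_grid(d_corr, grid) else NULL

    runs <- list()
    for (smax in config$s_max_list) {
      say("  s_max = %.2f", smax)
      refs <- generate_reflection_set(config$cell, smax, config$friedel)
      blocks <- ft_ao_pair_integrals(ints$basis, refs)
      refs <- make_reference_amplitudes(d_corr, refs, blocks)
      scan <- lambda_scan(mol, config$basis, refs, lambdas = config$lambdas,
                          blocks = blocks, ints = ints)
      rows <- lapply(scan, function(r) {
        ti <- vapply(names(bonds), function(bn) {
          b <- bonds[[bn]]
          cp <- tryCatch(find_bcp(r$density, b[1], b[2]), error = function(e) NULL)
          if (is.null(cp)) return(NA_real_)
          topological_index(cp$rho, bcp_rhf[[bn]]$rho, bcp_corr[[bn]]$rho)
        }, 0)
        extra <- if (config$with_fields) {
          fM <- density_on_grid(r$density, grid)
          rm_ <- rmsd_mad(fM, f_corr)
          c(rsr = rsr(fM, f_corr), carbo = carbo_distance(fM, f_corr),
            rmsd = rm_[["rmsd"]], mad = rm_[["mad"]])
        } else c(rsr = NA_real_, carbo = NA_real_, rmsd = NA_real_, mad = NA_real_)
        data.frame(molecule = mname, s_max = smax, lambda = r$lambda,
                   E0 = r$E0, chi2 = r$chi2, converged = r$converged,
                   t(ti), t(extra), check.names = FALSE)
      })
      runs[[sprintf("%.2f", smax)]] <- list(refs = refs, scan = scan,
                                            table = do.call(rbind, rows))
    }
    # attachment/detachment summary: promoted electrons for the correlated
    # reference and for the largest-lambda constrained state per s_max
    p_corr <- attach_detach_decomposition(d_rhf, d_corr)$p
    p_xc <- vapply(runs, function(rn) {
      last <- rn$scan[[length(rn$scan)]]
      attach_detach_decomposition(d_rhf$P, last$P, ints$S)$p
    }, 0)
    out[[mname]] <- list(molecule = mol, bonds = bonds,
                         rhf = d_rhf, corr = d_corr,
                         bcp_rhf = bcp_rhf, bcp_corr = bcp_corr,
                         runs = runs, p_corr = p_corr, p_xc = p_xc)
  }
  structure(list(results = out, config = config), class = "xcw_study")
}

#' Report tables from a study
#'
#' Reshapes the study results into the wide layout of the paper-style TI
#' tables: one table per (molecule, bond), rows = lambda, columns = s_max.
#'
#' @param study an [run_study()] result.
#' @param dir optional output directory; when given, one CSV per table plus
#'   a combined long-format CSV are written.
#' @return Named list of wide data frames (invisible when writing).
#' @export
make_report_tables <- function(study, dir = NULL) {
  tabs <- list()
  long <- list()
  for (mname in names(study$results)) {
    res <- study$results[[mname]]
    full <- do.call(rbind, lapply(res$runs, `[[`, "table"))
    long[[mname]] <- full
    for (bn in names(res$bonds)) {
      wide <- stats::reshape(
        full[, c("lambda", "s_max", bn)],
        idvar = "lambda", timevar = "s_max", direction = "wide")
      names(wide) <- sub(paste0("^", bn, "\\."), "s_max=", names(wide))
      tabs[[paste(mname, bn, sep = ": ")]] <- wide
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tabs)) {
      utils::write.csv(tabs[[nm]],
                       file.path(dir, paste0("TI_", gsub("[: ]+", "_", nm), ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(do.call(rbind, long), file.path(dir, "study_long.csv"),
                     row.names = FALSE)
    return(invisible(tabs))
  }
  tabs
}

#' @export
print.xcw_study <- function(x, ...) {
  cat(sprintf("<study: %s | basis %s | %d resolutions x %d lambda points>\n",
              paste(names(x$results), collapse = ", "), x$config$basis,
              length(x$config$s_max_list), length(x$config$lambdas)))
  invisible(x)
}
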