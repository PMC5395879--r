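#' Sweep grids over diameter, malacic length and severity
#'
#' `anterior_sweep_grid()` spans the anterior cartilage-weakening study
#' (diameters 6/8/10 mm, severities soft/mucosa, 0/1/3/5/7 centered rings);
#' `posterior_sweep_grid()` spans the trachealis-weakening study (malacic
#' lengths 2-32 mm with replacement coefficients (a = 1, b = 7) and
#' (a = 1, b = 1)).
#'
#' @param diameters Lumen diameters, mm.
#' @param severities Anterior severities.
#' @param rings Anterior ring counts (odd, or 0 for intact).
#' @return A tibble, one row per sweep cell.
#' @export
anterior_sweep_grid <- function(diameters = c(6, 8, 10),
                                severities = c("soft", "mucosa"),
                                rings = c(0, 1, 3, 5, 7)) {
  g <- tidyr::expand_grid(diameter = diameters, severity = severities,
                          rings = rings)
  g$target <- "anterior"
  g$length_mm <- malacic_length(g$rings)
  g$a <- NA_real_; g$b <- NA_real_
  g[, c("target", "diameter", "severity", "rings", "length_mm", "a", "b")]
}

#' @rdname anterior_sweep_grid
#' @param lengths Posterior malacic lengths, mm.
#' @param coefficients List of replacement `(a, b)` pairs for the muscle.
#' @export
posterior_sweep_grid <- function(diameters = 10,
                                 lengths = c(2, 8, 14, 20, 26, 32),
                                 coefficients = list(c(1, 7), c(1, 1))) {
  ab <- do.call(rbind, coefficients)
  g <- tidyr::expand_grid(diameter = diameters, coef = seq_len(nrow(ab)),
                          length_mm = lengths)
  g$target <- "posterior"
  g$severity <- "posterior"
  g$rings <- NA_integer_
  g$a <- ab[g$coef, 1]; g$b <- ab[g$coef, 2]
  g[, c("target", "diameter", "severity", "rings", "length_mm", "a", "b")]
}

#' Run a collapse sweep
#'
#' One simulation per grid cell; per-cell collapse curve, instability
#' report and wall-strain summary. Cells that fail under load control are
#' recorded as non-convergent collapse; unexpected errors are logged and
#' the sweep continues.
#'
#' @param grid A grid from [anterior_sweep_grid()] /
#'   [posterior_sweep_grid()] (rows may be mixed).
#' @param library A [tissue_library()].
#' @param program A [load_program()].
#' @param config A [solver_config()].
#' @param mesh_args Extra arguments to [trachea_config()] (mesh densities).
#' @param delta Instability threshold passed to [detect_instability()].
#' @param verbose Print per-cell progress.
#' @return A `sweep_result` tibble: the grid plus `termination`, `onset`,
#'   `onset_force_n`, `final_area_ratio`, `max_strain`, and list-columns
#'   `curve` and `report`.
#' @export
run_sweep <- function(grid, library = default_tissue_library(),
                      program = load_program(), config = solver_config(),
                      mesh_args = list(), delta = 0.05, verbose = FALSE) {
  meshes <- list()
  get_mesh <- function(d) {
    key <- as.character(d)
    if (is.null(meshes[[key]])) {
      cfg <- do.call(trachea_config, c(list(diameter = d), mesh_args))
      meshes[[key]] <<- build_trachea_mesh(cfg)
    }
    meshes[[key]]
  }
  out <- grid
  out$termination <- NA_character_
  out$onset <- NA
  out$onset_force_n <- NA_real_
  out$final_area_ratio <- NA_real_
  out$max_strain <- NA_real_
  out$curve <- vector("list", nrow(grid))
  out$report <- vector("list", nrow(grid))

  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    if (verbose)
      message(sprintf("[%d/%d] D=%g %s %s extent=%g mm", i, nrow(grid),
                      row$diameter, row$target, row$severity, row$length_mm))
    cell <- tryCatch({
      mesh <- get_mesh(row$diameter)
      mal <- if (row$target == "anterior") {
        if (row$rings == 0) NULL
        else malacia_spec("anterior", severity = row$severity, rings = row$rings)
      } else {
        malacia_spec("posterior", length_mm = row$length_mm,
                     a = row$a, b = row$b)
      }
      res <- run_load_program(mesh, library, program, config, malacia = mal)
      curve <- area_ratio_curve(res, mesh)
      rep <- detect_instability(curve, delta = delta,
                                termination = res$termination)
      lib_s <- if (identical(config$element, "h8i")) library else NULL
      strain <- max(element_strains(mesh, res$states[[length(res$states)]]$u,
                                    library = lib_s, malacia = mal)[, 1])
      list(termination = res$termination, curve = curve, report = rep,
           strain = strain)
    }, error = function(e) list(termination = "error", curve = NULL,
                                report = NULL, strain = NA_real_,
                                msg = conditionMessage(e)))
    out$termination[i] <- cell$termination
    out$curve[[i]] <- cell$curve
    out$report[[i]] <- cell$report
    out$max_strain[i] <- cell$strain
    if (!is.null(cell$report)) {
      out$onset[i] <- cell$report$onset
      out$onset_force_n[i] <- cell$report$force_n
    }
    if (!is.null(cell$curve))
      out$final_area_ratio[i] <- cell$curve$area_ratio[nrow(cell$curve)]
  }
  class(out) <- c("sweep_result", class(out))
  out
}
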