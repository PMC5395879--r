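#' Load program
#'
#' Exhalation is modeled as a net inward (external minus internal) pressure
#' on the luminal surface ramped from 0 to `max_pressure`, with converged
#' states recorded at every `output_interval` multiple.
#'
#' @param max_pressure Maximum pressure, cm H2O (default 40).
#' @param output_interval Output cadence, cm H2O (default 4).
#' @param follower Treat the pressure as a follower load on the deformed
#'   surface (default TRUE).
#' @return A `load_program` list.
#' @export
load_program <- function(max_pressure = 40, output_interval = 4,
                         follower = TRUE) {
  stopifnot(max_pressure >= 0, output_interval > 0)
  structure(list(max_pressure = max_pressure,
                 output_interval = output_interval, follower = follower),
            class = "load_program")
}

#' Solver configuration
#'
#' @param tol_res Relative residual tolerance (default 1e-6).
#' @param tol_du Displacement-increment tolerance (default 1e-8).
#' @param max_iter Newton iterations per substep (default 25).
#' @param ds_init,ds_min,ds_max Initial / minimum / maximum load substep in
#'   cm H2O (defaults 1, 1e-3, equal to the output interval).
#' @param grow Substep growth factor after easy convergence (default 1.5).
#' @param contact Enable luminal self-contact (default TRUE).
#' @param penalty Contact penalty stiffness, MPa/mm; default
#'   `100 * max(a) / mucosa_thickness` over the model's materials.
#' @param continuation `"load_control"` (terminates with
#'   `non_convergence_collapse` when the substep underflows at a limit
#'   point) or `"arc_length"` (traverses the limit point and continues onto
#'   the post-buckled branch).
#' @param arc_method `"crisfield"` (cylindrical arc-length constraint) or
#'   `"dof_control"` (prescribed increment of a single control dof with the
#'   load factor unknown).
#' @param arc_ds Initial arc increment, mm of displacement (default 0.25).
#' @param arc_steps Maximum continuation steps (default 400).
#' @param du_max Per-iteration cap on the largest displacement-component
#'   update, mm (damped Newton; limits unphysical branch jumps at limit
#'   points under load control). Default 1.
#' @param post_limit_stop Optional pressure (cm H2O): with arc-length
#'   continuation, stop once the load has passed its limit point, dipped
#'   below this level and risen back through it on the post-buckled branch.
#' @param element `"h8i"` (8-node hexahedra with three incompatible bending
#'   modes, statically condensed -- accurate in thin-wall bending at coarse
#'   meshes) or `"h8"` (plain trilinear).
#' @return A `solver_config` list.
#' @export
solver_config <- function(tol_res = 1e-6, tol_du = 1e-8, max_iter = 25,
                          ds_init = 1, ds_min = 1e-3, ds_max = NULL,
                          grow = 1.5, contact = TRUE, penalty = NULL,
                          continuation = c("load_control", "arc_length"),
                          arc_method = c("dof_control", "crisfield"),
                          arc_ds = 0.25, arc_steps = 400, du_max = 1,
                          post_limit_stop = NULL,
                          element = c("h8i", "h8")) {
  stopifnot(tol_res > 0, tol_du > 0, ds_min > 0, du_max > 0)
  structure(list(tol_res = tol_res, tol_du = tol_du, max_iter = max_iter,
                 ds_init = ds_init, ds_min = ds_min, ds_max = ds_max,
                 grow = grow, contact = contact, penalty = penalty,
                 continuation = match.arg(continuation),
                 arc_method = match.arg(arc_method),
                 arc_ds = arc_ds, arc_steps = arc_steps, du_max = du_max,
                 post_limit_stop = post_limit_stop,
                 element = match.arg(element)),
            class = "solver_config")
}

# sparse linear solve: symmetrized Cholesky (the internal tangent is
# symmetric; follower-load and contact asymmetries are small) with a
# verified residual, falling back to sparse LU on failure or indefiniteness
solve_lin <- function(K, B) {
  B <- as.matrix(B)
  Ks <- tryCatch(Matrix::forceSymmetric((K + Matrix::t(K)) / 2),
                 error = function(e) NULL)
  if (!is.null(Ks)) {
    ch <- tryCatch(suppressWarnings(Matrix::Cholesky(Ks, LDL = TRUE, perm = TRUE)),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      x <- tryCatch(as.matrix(Matrix::solve(ch, B)), error = function(e) NULL)
      if (!is.null(x) && all(is.finite(x))) {
        # validate the factorization against the symmetrized operator; the
        # (small) asymmetric remainder only perturbs the Newton direction
        res <- max(abs(Ks %*% x - B))
        if (res <= 1e-7 * (max(abs(B)) + 1e-12)) return(x)
      }
    }
  }
  as.matrix(Matrix::solve(K, B))
}

# ---- generic nonlinear system interface --------------------------------
# A system is a list with: ndof, free, fixed, fixed_values, control_dof
# (optional) and assemble(u, lam, want_K) returning list(ok, r, K, q, diag).
# Residual convention: r(u, lam) = f_int(u) + f_contact(u) - lam * q(u).

newton_step <- function(sys, u, lam, cfg) {
  u[sys$fixed] <- lam * sys$fixed_values
  snap <- if (!is.null(sys$snapshot_state)) sys$snapshot_state() else NULL
  fail <- function(reason, u, it) {
    if (!is.null(snap)) sys$restore_state(snap)
    list(ok = FALSE, reason = reason, u = u, iters = it)
  }
  res_hist <- NA_real_
  for (it in seq_len(cfg$max_iter)) {
    asm <- sys$assemble(u, lam, want_K = TRUE)
    if (!asm$ok) return(fail("inverted", u, it))
    r_f <- asm$r[sys$free]
    ref <- max(sqrt(sum((lam * asm$q[sys$free])^2)),
               sqrt(sum(asm$f_int[sys$free]^2)),
               0.01 * sqrt(sum(asm$q[sys$free]^2)), 1e-9)
    rn <- sqrt(sum(r_f^2))
    if (!is.finite(rn)) return(fail("nan", u, it))
    if (rn <= cfg$tol_res * ref)
      return(list(ok = TRUE, u = u, iters = it, res = rn / ref, diag = asm$diag))
    if (it > 3 && rn > 1e4 * res_hist)
      return(fail("diverged", u, it))
    if (is.na(res_hist) || rn < res_hist) res_hist <- rn
    du <- tryCatch(
      as.numeric(solve_lin(asm$K[sys$free, sys$free, drop = FALSE], -r_f)),
      error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(fail("singular", u, it))
    dmax <- max(abs(du))
    if (dmax > cfg$du_max) du <- du * (cfg$du_max / dmax)
    # residual backtracking: tames contact set changes and folding states
    if (isTRUE(asm$diag$n_contact > 0) || rn > 10 * ref) {
      step_sc <- 1
      for (bt in 1:4) {
        ut <- u
        ut[sys$free] <- u[sys$free] + step_sc * du
        at <- sys$assemble(ut, lam, want_K = FALSE)
        if (at$ok && sqrt(sum(at$r[sys$free]^2)) <= max(2 * rn, cfg$tol_res * ref))
          break
        step_sc <- step_sc / 2
      }
      du <- step_sc * du
    }
    u[sys$free] <- u[sys$free] + du
    if (sqrt(sum(du^2)) <= cfg$tol_du * max(sqrt(sum(u[sys$free]^2)), 1)) {
      asm2 <- sys$assemble(u, lam, want_K = FALSE)
      if (asm2$ok)
        return(list(ok = TRUE, u = u, iters = it, res = NA_real_,
                    diag = asm2$diag))
    }
  }
  fail("max_iter", u, cfg$max_iter)
}

# load-control driver with adaptive substeps; states recorded exactly at the
# requested target loads
solve_load_control <- function(sys, lam_max, targets, cfg) {
  u <- numeric(sys$ndof)
  states <- list(list(lam = 0, u = u, diag = list()))
  log <- list()
  if (lam_max <= 0)
    return(list(states = states, termination = "completed", log = log))
  dl <- min(cfg$ds_init, lam_max)
  ds_max <- if (is.null(cfg$ds_max)) max(targets[1], cfg$ds_init) else cfg$ds_max
  lam <- 0
  # always record the terminal load even when it is not an output multiple
  pending <- sort(unique(c(targets[targets > 1e-12], lam_max)))
  step_id <- 0L
  while (lam < lam_max - 1e-12) {
    lam_try <- min(lam + dl, lam_max, if (length(pending)) pending[1] else Inf)
    st <- newton_step(sys, u, lam_try, cfg)
    step_id <- step_id + 1L
    log[[step_id]] <- list(step = step_id, pressure = lam_try, ok = st$ok,
                           iterations = st$iters,
                           residual = if (st$ok && !is.null(st$res)) st$res else NA_real_,
                           reason = if (st$ok) "converged" else st$reason)
    if (st$ok) {
      u <- st$u
      lam <- lam_try
      if (length(pending) && abs(lam - pending[1]) < 1e-9) {
        states[[length(states) + 1L]] <- list(lam = lam, u = u, diag = st$diag)
        pending <- pending[-1]
      }
      if (st$iters <= 6) dl <- min(dl * cfg$grow, ds_max)
    } else {
      dl <- dl / 2
      if (dl < cfg$ds_min) {
        # record the last converged state as the terminal one
        if (abs(states[[length(states)]]$lam - lam) > 1e-9)
          states[[length(states) + 1L]] <- list(lam = lam, u = u, diag = list())
        return(list(states = states, termination = "non_convergence_collapse",
                    log = log))
      }
    }
  }
  list(states = states, termination = "completed", log = log)
}

# continuation driver (arc-length): unknown load factor, bordered solves.
# With post_limit_stop set, the run continues through the limit point and
# terminates once the load factor has dipped below the stop level and risen
# back through it on the post-buckled branch (the far stable equilibrium a
# quasi-static snap at that load would reach).
solve_continuation <- function(sys, lam_max, cfg) {
  u <- numeric(sys$ndof)
  lam <- 0
  states <- list(list(lam = 0, u = u, diag = list()))
  log <- list()
  ds <- cfg$arc_ds
  du_prev <- NULL
  dlam_prev <- NULL
  limit_passed <- FALSE
  lam_peak <- 0
  pls <- cfg$post_limit_stop
  lam_min_post <- Inf
  cdof_free <- if (!is.null(sys$control_dof))
    match(sys$control_dof, sys$free) else NA_integer_
  if (cfg$arc_method == "dof_control" && is.na(cdof_free))
    stop("dof_control continuation needs a control dof among the free dofs")
  csign <- if (!is.null(sys$control_sign)) sys$control_sign else 1

  for (step in seq_len(cfg$arc_steps)) {
    attempt_ok <- FALSE
    for (cut in 0:10) {
      res <- arc_corrector(sys, u, lam, ds, du_prev, dlam_prev, cfg,
                           cdof_free, csign)
      if (res$ok) { attempt_ok <- TRUE; break }
      ds <- ds / 2
      if (ds < 1e-9) break
    }
    log[[step]] <- list(step = step, pressure = if (attempt_ok) res$lam else lam,
                        ok = attempt_ok,
                        iterations = if (attempt_ok) res$iters else NA_integer_,
                        reason = if (attempt_ok) "converged" else "cutback_floor")
    if (!attempt_ok)
      return(list(states = states, termination = "non_convergence_collapse",
                  log = log, limit_passed = limit_passed, lam_peak = lam_peak))
    du_prev <- res$u - u
    dlam_prev <- res$lam - lam
    u <- res$u
    lam <- res$lam
    if (lam < lam_peak - 1e-9) limit_passed <- TRUE
    lam_peak <- max(lam_peak, lam)
    if (limit_passed) lam_min_post <- min(lam_min_post, lam)
    states[[length(states) + 1L]] <- list(lam = lam, u = u, diag = res$diag)
    if (res$iters <= 6) ds <- ds * cfg$grow else if (res$iters > 12) ds <- ds / 1.5
    done <- lam >= lam_max - 1e-9 ||
      (!is.null(pls) && limit_passed && lam_min_post < pls && lam >= pls)
    if (done)
      return(list(states = states, termination = "completed", log = log,
                  limit_passed = limit_passed, lam_peak = lam_peak))
  }
  list(states = states, termination = "max_steps", log = log,
       limit_passed = limit_passed, lam_peak = lam_peak)
}

arc_corrector <- function(sys, u0, lam0, ds, du_prev, dlam_prev, cfg,
                          cdof_free, csign) {
  free <- sys$free
  snap <- if (!is.null(sys$snapshot_state)) sys$snapshot_state() else NULL
  fail <- function() {
    if (!is.null(snap)) sys$restore_state(snap)
    list(ok = FALSE)
  }
  # predictor
  asm <- sys$assemble(u0, lam0, want_K = TRUE)
  if (!asm$ok) return(fail())
  Kff <- asm$K[free, free, drop = FALSE]
  duq <- tryCatch(as.numeric(solve_lin(Kff, asm$q[free])),
                  error = function(e) NULL)
  if (is.null(duq) || any(!is.finite(duq))) return(fail())
  if (is.null(du_prev)) {
    if (cfg$arc_method == "dof_control") {
      # linear estimate that already satisfies the control-dof constraint
      dlam <- csign * ds / duq[cdof_free]
      Du <- dlam * duq
    } else {
      dlam <- ds / sqrt(sum(duq^2) + 1)
      Du <- dlam * duq
    }
  } else if (cfg$arc_method == "dof_control") {
    prev_c <- du_prev[free][cdof_free]
    sc <- if (abs(prev_c) > 1e-14) csign * ds / prev_c
          else csign * ds / duq[cdof_free] / max(dlam_prev, 1e-12)
    Du <- sc * du_prev[free]
    dlam <- sc * dlam_prev
  } else {
    sc <- ds / max(sqrt(sum(du_prev[free]^2)), 1e-12)
    Du <- sc * du_prev[free]
    dlam <- sc * dlam_prev
  }
  u <- u0
  u[free] <- u0[free] + Du
  lam <- lam0 + dlam
  Du_full <- function(u) u[free] - u0[free]

  for (it in seq_len(cfg$max_iter)) {
    u[sys$fixed] <- lam * sys$fixed_values
    asm <- sys$assemble(u, lam, want_K = TRUE)
    if (!asm$ok) return(fail())
    r_f <- asm$r[free]
    # the floor keeps the tolerance attainable near the unloaded state
    # (0.01 units of the external load vector)
    ref <- max(sqrt(sum((lam * asm$q[free])^2)),
               sqrt(sum(asm$f_int[free]^2)),
               0.01 * sqrt(sum(asm$q[free]^2)), 1e-9)
    if (sqrt(sum(r_f^2)) <= cfg$tol_res * ref)
      return(list(ok = TRUE, u = u, lam = lam, iters = it, diag = asm$diag))
    Kff <- asm$K[free, free, drop = FALSE]
    sol <- tryCatch(
      solve_lin(Kff, cbind(-r_f, asm$q[free])),
      error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) return(fail())
    dur <- sol[, 1]; duq <- sol[, 2]
    Du <- Du_full(u)
    if (cfg$arc_method == "dof_control") {
      denom <- duq[cdof_free]
      if (abs(denom) < 1e-14) return(fail())
      dlam_i <- (csign * ds - Du[cdof_free] - dur[cdof_free]) / denom
    } else {
      a <- sum(duq^2)
      bq <- 2 * sum((Du + dur) * duq)
      cc <- sum((Du + dur)^2) - ds^2
      disc <- bq^2 - 4 * a * cc
      if (!is.finite(disc) || disc < 0) return(fail())
      r1 <- (-bq + sqrt(disc)) / (2 * a)
      r2 <- (-bq - sqrt(disc)) / (2 * a)
      pick <- function(dl) sum((Du + dur + dl * duq) * Du)
      dlam_i <- if (pick(r1) >= pick(r2)) r1 else r2
    }
    step <- dur + dlam_i * duq
    smax <- max(abs(step))
    if (smax > cfg$du_max) {
      # damped correction; scale the load update consistently
      sc <- cfg$du_max / smax
      step <- step * sc
      dlam_i <- dlam_i * sc
    }
    # residual backtracking against contact chattering
    rn0 <- sqrt(sum(r_f^2))
    step_sc <- 1
    if (isTRUE(asm$diag$n_contact > 0) || rn0 > 10 * ref) {
      for (bt in 1:4) {
        ut <- u
        ut[free] <- u[free] + step_sc * step
        at <- sys$assemble(ut, lam + step_sc * dlam_i, want_K = FALSE)
        if (at$ok && sqrt(sum(at$r[free]^2)) <= max(2 * rn0, cfg$tol_res * ref))
          break
        step_sc <- step_sc / 2
      }
    }
    u[free] <- u[free] + step_sc * step
    lam <- lam + step_sc * dlam_i
  }
  fail()
}

# ---- FE system construction --------------------------------------------

# map mesh region labels to tissue-library roles
region_role <- c(cartilage = "cartilage", fibrous = "fibrous",
                 muscle = "smooth_muscle", mucosa = "mucosa")

assign_materials <- function(mesh, library, malacia = NULL) {
  roles <- region_role[mesh$region]
  mats <- library[unique(roles)]
  mat_id <- match(roles, names(mats))
  if (!is.null(malacia)) {
    sel <- select_malacic_elements(mesh, malacia)
    if (length(sel)) {
      lib_mal <- if (malacia$target == "anterior")
        apply_malacia(library, malacia$severity)
      else
        apply_malacia(library, "posterior", a = malacia$a, b = malacia$b)
      for (role in unique(roles[sel])) {
        m <- lib_mal[[role]]
        mats[[paste0(role, "_malacic")]] <- m
        mat_id[sel][roles[sel] == role] <-
          which(names(mats) == paste0(role, "_malacic"))
      }
    }
  }
  list(materials = mats, elem_mat = mat_id)
}

fe_system <- function(nodes, elems, materials, elem_mat, fixed, fixed_values,
                      facets = NULL, follower = TRUE, contact = FALSE,
                      penalty = 0, cap = Inf, control_dof = NULL,
                      control_sign = 1, enhanced = TRUE) {
  ndof <- 3L * nrow(nodes)
  free <- setdiff(seq_len(ndof), fixed)
  mat_a <- lapply(materials, `[[`, "a")
  mat_b <- lapply(materials, `[[`, "b")
  kap <- vapply(materials, `[[`, numeric(1), "bulk_modulus")
  elems0 <- elems - 1L
  storage.mode(elems0) <- "integer"
  facets0 <- if (!is.null(facets)) facets - 1L else matrix(0L, 0, 4)
  storage.mode(facets0) <- "integer"
  p_unit <- CMH2O_MPA  # load factor in cm H2O
  pat <- .asm_pattern_cpp(elems0, facets0, nrow(nodes))
  # persistent warm start for the condensed incompatible-mode dofs
  alpha_store <- matrix(0, 9, if (enhanced) nrow(elems0) else 0)

  assemble <- function(u, lam, want_K) {
    xval <- if (want_K) numeric(pat$nnz) else numeric(0)
    asm <- .asm_internal_fill_cpp(nodes, elems0, u, mat_a, mat_b, kap,
                                  elem_mat - 1L, pat$map_e, xval, want_K,
                                  enhanced, alpha_store)
    if (!asm$ok) return(list(ok = FALSE))
    r <- asm$f
    q <- numeric(ndof)
    diag <- list(min_detF = asm$min_detF, energy = asm$energy,
                 n_contact = 0L, max_penetration = 0)
    if (nrow(facets0) > 0) {
      pr <- .asm_pressure_fill_cpp(nodes, facets0, u, p_unit, follower,
                                   pat$map_f, xval, -lam, want_K)
      q <- pr$f
      r <- r - lam * q
    }
    K <- NULL
    if (want_K)
      K <- methods::new("dgCMatrix", i = pat$i, p = pat$p, x = xval,
                        Dim = c(ndof, ndof))
    if (contact && nrow(facets0) > 0) {
      ct <- .asm_contact_cpp(nodes, facets0, u, penalty, cap, want_K)
      r <- r + ct$f
      if (want_K && ct$n_active > 0) K <- K + ct$K
      diag$n_contact <- ct$n_active
      diag$max_penetration <- ct$max_penetration
      if (ct$max_penetration > 0.9 * cap) return(list(ok = FALSE))
    }
    list(ok = TRUE, r = r, K = K, q = q, f_int = asm$f, diag = diag)
  }

  # the condensed-mode warm-start store must track *accepted* states only;
  # drivers snapshot it before an attempt and restore it on failure
  snapshot_state <- function() alpha_store + 0
  restore_state <- function(s) alpha_store[] <<- s

  list(ndof = ndof, free = free, fixed = fixed, fixed_values = fixed_values,
       assemble = assemble, control_dof = control_dof,
       control_sign = control_sign,
       snapshot_state = snapshot_state, restore_state = restore_state)
}

trachea_bcs <- function(mesh) {
  s <- mesh$sets
  dz <- function(ids) 3 * (ids - 1) + 3
  dx <- function(ids) 3 * (ids - 1) + 1
  dy <- function(ids) 3 * (ids - 1) + 2
  ends <- union(s$end_z0, s$end_zL)
  fixed <- c(dz(ends), dx(s$sym_plane), dy(intersect(s$muscle_midline, ends)))
  sort(unique(fixed))
}

#' Run the exhalation load program on a trachea model
#'
#' Assembles the total-Lagrangian hyperelastic model (selective reduced
#' volumetric integration, follower pressure on the luminal surface,
#' frictionless penalty self-contact) and advances it through the load
#' program with adaptive Newton stepping. Under `load_control` a substep
#' underflow at a limit point terminates with `non_convergence_collapse`
#' (the behavior severe malacic cases exhibit); `arc_length` continuation
#' instead traverses the limit point onto the post-buckled branch.
#'
#' Boundary conditions: both end cross-sections are fixed axially, the
#' x = 0 symmetry plane is fixed laterally, and the muscle midline nodes of
#' the end sections are fixed vertically to remove rigid-body modes.
#'
#' @param mesh A [build_trachea_mesh()] result.
#' @param library A [tissue_library()].
#' @param program A [load_program()].
#' @param config A [solver_config()].
#' @param malacia Optional [malacia_spec()].
#' @return A `simulation_result`: list with `states` (each holding the
#'   pressure in cm H2O, the displacement vector and contact diagnostics),
#'   `termination` (`"completed"`, `"non_convergence_collapse"`,
#'   `"max_steps"` or `"error"`), a step `log` tibble, and the inputs.
#' @export
run_load_program <- function(mesh, library = default_tissue_library(),
                             program = load_program(),
                             config = solver_config(), malacia = NULL) {
  stopifnot(inherits(mesh, "trachea_mesh"))
  am <- assign_materials(mesh, library, malacia)
  pen <- config$penalty
  if (is.null(pen))
    pen <- 100 * max(vapply(am$materials, function(m) max(m$a), numeric(1))) /
      mesh$config$mucosa_thickness
  fixed <- trachea_bcs(mesh)
  # control dof: vertical displacement of the anterior apex at mid-length
  apex <- mesh$mid_loop[which.max(mesh$nodes[mesh$mid_loop, 2])]
  sys <- fe_system(mesh$nodes, mesh$elems, am$materials, am$elem_mat,
                   fixed = fixed, fixed_values = numeric(length(fixed)),
                   facets = mesh$lumen_facets, follower = program$follower,
                   contact = config$contact, penalty = pen,
                   cap = mesh$config$mucosa_thickness,
                   control_dof = 3 * (apex - 1) + 2, control_sign = -1,
                   enhanced = identical(config$element, "h8i"))
  targets <- if (program$max_pressure >= program$output_interval)
    seq(program$output_interval, program$max_pressure,
        by = program$output_interval)
  else program$max_pressure
  if (is.null(config$ds_max)) config$ds_max <- program$output_interval
  out <- if (config$continuation == "load_control")
    solve_load_control(sys, program$max_pressure, targets, config)
  else
    solve_continuation(sys, program$max_pressure, config)
  states <- lapply(out$states, function(s)
    list(pressure = s$lam, u = s$u,
         contact_active = isTRUE(s$diag$n_contact > 0),
         n_contact = if (is.null(s$diag$n_contact)) 0L else s$diag$n_contact))
  log <- dplyr::bind_rows(lapply(out$log, tibble::as_tibble))
  structure(list(states = states, termination = out$termination, log = log,
                 limit_passed = isTRUE(out$limit_passed),
                 lam_peak = out$lam_peak,
                 mesh = mesh, program = program, config = config,
                 malacia = malacia, library = library),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d states, final pressure %.3g cm H2O, termination: %s\n",
    length(x$states), x$states[[length(x$states)]]$pressure, x$termination))
  invisible(x)
}

#' Per-element principal Green-Lagrange strains
#'
#' Principal values of \eqn{E = (F^T F - I)/2}; the first column (maximum
#' principal strain) is the reported "wall strain". By default strains are
#' evaluated at the eight element corners and the extreme principal values
#' are reported, the analog of a nodal fringe plot: with one element through
#' a bending wall, a centroid evaluation sits on the neutral fiber and
#' misses the bending strain entirely. `at = "centroid"` gives the centroid
#' values instead. When a tissue `library` is supplied, the deformation
#' gradient includes the statically condensed incompatible bending modes
#' (recomputed deterministically from the displacement field).
#'
#' @param mesh A mesh with `nodes` and `elems`.
#' @param displacements Displacement vector, length `3 * n_nodes`.
#' @param library Optional [tissue_library()] (enables the enhanced-mode
#'   contribution for meshes solved with `element = "h8i"`).
#' @param malacia Optional [malacia_spec()] matching the solved model.
#' @param at `"corners"` (default) or `"centroid"`.
#' @return Matrix (n_elements x 3) of principal strains, descending.
#' @export
element_strains <- function(mesh, displacements, library = NULL,
                            malacia = NULL, at = c("corners", "centroid")) {
  at <- match.arg(at)
  elems0 <- mesh$elems - 1L
  storage.mode(elems0) <- "integer"
  ne <- nrow(elems0)
  if (!is.null(library)) {
    am <- assign_materials(mesh, library, malacia)
    .elem_strains_cpp(mesh$nodes, elems0, displacements,
                      as.integer(at == "corners"), 1L,
                      lapply(am$materials, `[[`, "a"),
                      lapply(am$materials, `[[`, "b"),
                      vapply(am$materials, `[[`, numeric(1), "bulk_modulus"),
                      am$elem_mat - 1L)
  } else {
    .elem_strains_cpp(mesh$nodes, elems0, displacements,
                      as.integer(at == "corners"), 0L,
                      list(1), list(1), 1, rep(0L, ne))
  }
}
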