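#' Options for the prioritized and baseline solvers
#'
#' @param feas_tol relative constraint-violation tolerance (per-constraint,
#'   scaled by its limit) accepted as feasible.
#' @param rho0 initial augmented-Lagrangian penalty weight.
#' @param outer_max maximum augmented-Lagrangian (multiplier) updates per
#'   optimization step.
#' @param inner_maxit L-BFGS-B iteration cap per inner solve.
#' @param dv_rounds maximum hot-voxel-exemption rounds per dose-volume
#'   objective.
#' @param two_pass run the second pass that re-minimizes ("supersedes")
#'   objectives that met their goals.
#' @param constraint_margin relative interior margin: each step is solved
#'   against limits tightened by this fraction, so the augmented-Lagrangian
#'   residual still lands strictly inside the true limits.
#' @param verbose print per-step progress.
#' @return list of solver options.
#' @export
plan_options <- function(feas_tol = 1e-5, rho0 = 50, outer_max = 6,
                         inner_maxit = 150, dv_rounds = 10, two_pass = TRUE,
                         constraint_margin = 2e-3, verbose = FALSE) {
  list(feas_tol = feas_tol, rho0 = rho0, outer_max = outer_max,
       inner_maxit = inner_maxit, dv_rounds = dv_rounds, two_pass = two_pass,
       constraint_margin = constraint_margin, verbose = verbose)
}

# ---- constraint machinery -------------------------------------------------
# A constraint is list(type, rows, b, scale, params, label). Types:
#   linmax  : d[rows] <= b, voxel-wise
#   auxmax  : d[rows] <= t (the step's auxiliary max variable)
#   mean    : mean(d[rows]) <= b
#   eud     : geud(d[rows], k) <= b
#   logltcp : log LTCP(d[rows]) <= log(b)  (monotone transform of LTCP <= b)
# All are evaluated scaled by `scale` so tolerances are relative.

con_linmax <- function(rows, b, label)
  list(type = "linmax", rows = rows, b = b, scale = max(abs(b), 1),
       label = label)

con_scalar <- function(type, rows, b, label, params = list()) {
  # the log-LTCP bound is scaled by alpha * Dp: its violation can reach
  # O(alpha * Dp) log units at low dose, and dividing by that Lipschitz
  # scale conditions the constraint like the (d - b)/b dose caps; the
  # solver compensates with a proportionally larger penalty weight so the
  # multiplier ramp keeps its natural speed
  scale <- switch(type, logltcp = params$alpha * params$Dp, max(abs(b), 1))
  list(type = type, rows = rows, b = b, scale = scale, params = params,
       label = label)
}

con_g <- function(con, d, t_aux = NULL) {
  dr <- d[con$rows]
  switch(con$type,
    linmax = (dr - con$b) / con$scale,
    auxmax = (dr - t_aux) / con$scale,
    mean = (mean(dr) - con$b) / con$scale,
    eud = (.geud_raw(dr, con$params$k) - con$b) / con$scale,
    logltcp = (log_ltcp(dr, con$params$Dp, con$params$alpha) -
                 log(con$b)) / con$scale)
}

# add the constraint's contribution y' * dg/dd to the body-dose gradient
# accumulator; returns the auxiliary-variable gradient contribution
con_add_grad <- function(con, d, y, gd_env, t_aux = NULL) {
  rows <- con$rows
  dr <- d[rows]
  ga <- 0
  inc <- switch(con$type,
    linmax = y / con$scale,
    auxmax = { ga <- -sum(y) / con$scale; y / con$scale },
    mean = rep(y / (con$scale * length(rows)), length(rows)),
    eud = y * .geud_grad(dr, con$params$k) / con$scale,
    logltcp = y * (-con$params$alpha * .softmax_underdose(
      dr, con$params$Dp, con$params$alpha)) / con$scale)
  gd_env$gd[rows] <- gd_env$gd[rows] + inc
  ga
}

.geud_raw <- function(d, k) {
  mx <- max(d)
  if (mx == 0) return(0)
  mx * mean((d / mx)^k)^(1 / k)
}

.geud_grad <- function(d, k) {
  mx <- max(d)
  if (mx == 0) return(rep(0, length(d)))
  u <- d / mx
  s <- mean(u^k)
  (u^(k - 1) * s^(1 / k - 1)) / length(d)
}

.softmax_underdose <- function(d, Dp, alpha) {
  e <- -alpha * (d - Dp)
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

# ---- objective machinery --------------------------------------------------
# A step objective is list(kind, rows, params); value/grad on the body dose.
obj_value <- function(obj, d, t_aux = NULL) {
  dr <- d[obj$rows]
  switch(obj$kind,
    logltcp = log_ltcp(dr, obj$params$Dp, obj$params$alpha),
    mean = mean(dr),
    eud = .geud_raw(dr, obj$params$k),
    auxmax = t_aux,
    dv_hinge = {
      T0 <- obj$params$threshold
      mean(pmax(0, dr - T0)^2) / T0^2
    },
    # saturating coverage penalty for weighted-sum use: ~ (log LTCP - log
    # goal) while the goal is missed, ~ 0 once it is strongly met, so the
    # term is bounded below and cannot pay for unlimited overdosing
    ltcp_soft = {
      z <- log_ltcp(dr, obj$params$Dp, obj$params$alpha) -
        log(obj$params$goal)
      if (z > 30) z else log1p(exp(z))
    })
}

obj_add_grad <- function(obj, d, gd_env, t_aux = NULL) {
  rows <- obj$rows
  dr <- d[rows]
  ga <- 0
  inc <- switch(obj$kind,
    logltcp = -obj$params$alpha *
      .softmax_underdose(dr, obj$params$Dp, obj$params$alpha),
    mean = rep(1 / length(rows), length(rows)),
    eud = .geud_grad(dr, obj$params$k),
    auxmax = { ga <- 1; rep(0, length(rows)) },
    dv_hinge = {
      T0 <- obj$params$threshold
      2 * pmax(0, dr - T0) / (length(rows) * T0^2)
    },
    ltcp_soft = {
      z <- log_ltcp(dr, obj$params$Dp, obj$params$alpha) -
        log(obj$params$goal)
      sig <- if (z > 30) 1 else exp(z) / (1 + exp(z))
      sig * (-obj$params$alpha *
               .softmax_underdose(dr, obj$params$Dp, obj$params$alpha))
    })
  gd_env$gd[rows] <- gd_env$gd[rows] + inc
  ga
}

# projected-gradient descent with Armijo backtracking: rescue for the rare
# points where L-BFGS-B's Wolfe line search aborts (sharp penalty valleys);
# only sufficient decrease is required, so it always makes progress on these
# convex subproblems
pgd_polish <- function(x, fn, gr, lower, maxit = 200L) {
  fx <- fn(x)
  t <- 1
  for (it in seq_len(maxit)) {
    g <- gr(x)
    moved <- FALSE
    for (bt in 1:40) {
      xn <- pmax(lower, x - t * g)
      step <- xn - x
      if (!any(step != 0)) break
      fxn <- fn(xn)
      if (fxn <= fx + 1e-4 * sum(g * step)) {
        x <- xn
        if (fx - fxn < 1e-10 * max(1, abs(fx))) { fx <- fxn; moved <- FALSE
          break }
        fx <- fxn
        t <- t * 1.8
        moved <- TRUE
        break
      }
      t <- t / 2
      if (t < 1e-14) break
    }
    if (!moved) break
  }
  x
}

# ---- augmented-Lagrangian step solver -------------------------------------
# Minimize obj subject to `cons`, fluence >= 0, starting from w0.
# Returns list(w, d, value, viol, converged).
solve_step <- function(A, w0, obj, cons, opts) {
  nb <- ncol(A)
  nvox <- nrow(A)
  has_aux <- identical(obj$kind, "auxmax")
  cons_true <- cons
  # interior margin: aim a hair inside every limit so the residual
  # infeasibility of the penalty method stays within the true limit. The
  # log-LTCP bound gets its margin in its own scaled units (a tenth of the
  # nominal margin), large enough to absorb the solver residual without
  # meaningfully tightening the coverage bound
  cons <- lapply(cons, function(cn) {
    if (cn$type == "auxmax") return(cn)
    if (cn$type == "logltcp")
      cn$b <- cn$b * exp(-0.1 * opts$constraint_margin * cn$scale)
    else cn$b <- cn$b * (1 - opts$constraint_margin)
    cn
  })
  d0 <- as.numeric(A %*% w0)
  t0 <- if (has_aux) max(d0[obj$rows]) else NULL
  f0 <- obj_value(obj, d0, t0)
  sf <- max(abs(f0), 1e-3)

  lam <- lapply(cons, function(cn) numeric(length(con_g(cn, d0, t0))))
  rho <- opts$rho0
  # per-constraint penalty multiplier: constraints whose g is divided by a
  # large Lipschitz scale get a proportionally larger weight, keeping the
  # penalty force in natural units while the curvature stays conditioned
  rho_mult <- vapply(cons, function(cn)
    if (cn$type == "logltcp") cn$scale else 1, 0)
  x <- c(w0, if (has_aux) t0)
  lower <- c(rep(0, nb), if (has_aux) 0)

  # closures for the augmented Lagrangian of `obj_use`; value and gradient
  # share one forward/transpose multiply via a small cache keyed on both the
  # point and the multiplier state (lam/rho change between outer iterations)
  al_version <- 0L
  hinge_cap <- 0.5
  make_fns <- function(obj_use) {
    cache <- new.env(parent = emptyenv())
    cache$x <- NULL
    evalx <- function(x) {
      if (!is.null(cache$x) && identical(cache$x, x) &&
          identical(cache$ver, al_version)) return()
      w <- x[seq_len(nb)]
      t_aux <- if (has_aux) x[nb + 1L] else NULL
      d <- as.numeric(A %*% w)
      fv <- obj_value(obj_use, d, t_aux) / sf
      gd_env <- new.env(parent = emptyenv())
      gd_env$gd <- numeric(nvox)
      ga <- obj_add_grad(obj_use, d, gd_env, t_aux) / sf
      gd_env$gd <- gd_env$gd / sf
      pen <- 0
      for (j in seq_along(cons)) {
        g <- con_g(cons[[j]], d, t_aux)
        # Huberized hinge: quadratic near the boundary, linear beyond
        # `hinge_cap` scaled units, so deep violations cannot build a
        # penalty wall too steep for the line search
        ge <- pmin(g, hinge_cap)
        rj <- rho * rho_mult[j]
        y <- pmax(0, lam[[j]] + rj * ge)
        pen <- pen + (sum(y^2) - sum(lam[[j]]^2)) / (2 * rj) +
          sum(y * pmax(0, g - hinge_cap))
        ga <- ga + con_add_grad(cons[[j]], d, y, gd_env, t_aux)
      }
      gw <- as.numeric(Matrix::crossprod(A, gd_env$gd))
      cache$x <- x
      cache$ver <- al_version
      cache$val <- fv + pen
      cache$grad <- c(gw, if (has_aux) ga)
      invisible()
    }
    list(fn = function(x) { evalx(x); cache$val },
         gr = function(x) { evalx(x); cache$grad })
  }
  fns <- make_fns(obj)
  fn <- fns$fn; gr <- fns$gr

  # smoothing continuation for the LTCP step: at the wish-list's alpha the
  # log-sum-exp is nearly a hard max over underdose and L-BFGS zigzags on the
  # coldest voxel; pre-solving with gentler alphas lifts the whole cold tail
  # first (each stage is convex, so only convergence speed is affected)
  if (identical(obj$kind, "logltcp")) {
    for (afrac in c(1 / 8, 1 / 2)) {
      obj_soft <- obj
      obj_soft$params$alpha <- obj$params$alpha * afrac
      soft <- make_fns(obj_soft)
      fit <- stats::optim(x, soft$fn, soft$gr, method = "L-BFGS-B",
                          lower = lower,
                          control = list(maxit = opts$inner_maxit,
                                         factr = 1e6))
      x <- fit$par
      if (fit$convergence == 52)
        x <- pgd_polish(x, soft$fn, soft$gr, lower)
    }
  }

  # residual tolerance per constraint, against the margined limits: a
  # residual comfortably inside each constraint's own margin shift is
  # feasible for the true limits (the shift in scaled units differs between
  # the dose caps and the log-scaled LTCP bound)
  mshift <- vapply(cons_true, function(cn) {
    if (cn$type == "auxmax") return(opts$constraint_margin)
    if (cn$type == "logltcp") 0.1 * opts$constraint_margin
    else opts$constraint_margin * abs(cn$b[1]) / cn$scale
  }, 0)
  tol_j <- pmax(opts$feas_tol, 0.25 * mshift)
  viol_prev <- Inf
  obj_prev <- Inf
  converged <- FALSE
  for (outer in seq_len(opts$outer_max)) {
    # L-BFGS-B can terminate early in flat maximin-like valleys; restart it
    # (fresh Hessian memory) while it keeps making real progress, and fall
    # back to projected gradient descent when its line search aborts
    val_prev <- Inf
    for (restart in 1:3) {
      fit <- stats::optim(x, fn, gr, method = "L-BFGS-B", lower = lower,
                          control = list(maxit = opts$inner_maxit,
                                         factr = 1e6))
      x <- fit$par
      if (fit$convergence == 52) {
        x <- pgd_polish(x, fn, gr, lower)
        fit$value <- fn(x)
      }
      if (val_prev - fit$value < 1e-5 * max(1, abs(fit$value))) break
      val_prev <- fit$value
    }
    w <- x[seq_len(nb)]
    t_aux <- if (has_aux) x[nb + 1L] else NULL
    d <- as.numeric(A %*% w)
    gs <- lapply(cons, con_g, d = d, t_aux = t_aux)
    viol <- if (length(gs)) max(0, unlist(gs, use.names = FALSE)) else 0
    within_tol <- all(vapply(seq_along(gs), function(j)
      max(gs[[j]]) <= tol_j[j], TRUE))
    obj_now <- obj_value(obj, d, t_aux) / sf
    # stop only when feasible (to the margined limits, per constraint) AND
    # the objective has stalled; multiplier updates continue otherwise
    if (within_tol &&
        obj_prev - obj_now < 1e-3 * max(1, abs(obj_now))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj_now
    lam <- Map(function(l, g, rm) pmax(0, l + rho * rm * pmin(g, hinge_cap)),
               lam, gs, rho_mult)
    if (viol > 0.7 * viol_prev) rho <- min(rho * 4, 1e5)
    viol_prev <- viol
    al_version <- al_version + 1L
  }
  w <- x[seq_len(nb)]
  d <- as.numeric(A %*% w)
  t_fin <- if (has_aux) max(d[obj$rows]) else NULL
  gs_true <- lapply(cons_true, con_g, d = d, t_aux = t_fin)
  viol_true <- if (length(gs_true))
    max(0, unlist(gs_true, use.names = FALSE)) else 0
  list(w = w, d = d,
       value = obj_value(obj, d, t_fin),
       viol = viol, viol_true = viol_true, converged = converged)
}

# map a wish-list objective row to its step-objective surrogate
step_objective <- function(ob, rows) {
  switch(ob$kind,
    "LTCP" = list(kind = "logltcp", rows = rows, params = ob$params),
    "mean" = list(kind = "mean", rows = rows, params = list()),
    "EUD" = list(kind = "eud", rows = rows, params = ob$params),
    "maximum" = list(kind = "auxmax", rows = rows, params = list()),
    "dose-volume" = list(kind = "dv_hinge", rows = rows, params = ob$params))
}

# bound constraint protecting a processed objective at value b
bound_constraint <- function(ob, rows, b, label) {
  switch(ob$kind,
    "LTCP" = con_scalar("logltcp", rows, b, label, ob$params),
    "mean" = con_scalar("mean", rows, b, label),
    "EUD" = con_scalar("eud", rows, b, label, ob$params),
    "maximum" = con_linmax(rows, b, label),
    "dose-volume" = NULL)  # handled by the exempt-set constraints
}

obj_label <- function(ob) sprintf("p%g %s %s", ob$priority, ob$volume, ob$kind)

# ---- prioritized solver ---------------------------------------------------

#' Solve the prioritized (wish-list) planning problem
#'
#' Lexicographic epsilon-constraint optimization of beamlet fluence: hard
#' maximum-dose constraints are always enforced; objectives are then
#' minimized one at a time in priority order, each previously processed
#' objective being frozen at a bound — its goal when the goal was met,
#' otherwise its attained value inflated by the relaxation slack — so that
#' lower priorities can only improve within the room the higher priorities
#' leave. A second pass re-minimizes objectives that met their goals
#' ("supersession") and tightens their bounds. Maximum-dose objectives are
#' exact voxel-wise linear inequalities via an auxiliary variable;
#' dose-volume objectives use iterative hot-voxel exemption: the hottest
#' goal-percent of the organ is exempted, the remaining voxels are
#' constrained to the threshold, and the exempt set is re-identified from
#' the new dose until stable. Each step is solved by an augmented-Lagrangian
#' loop over L-BFGS-B with nonnegative fluence.
#'
#' @param w a wish-list ([load_wishlist()]); resolved automatically.
#' @param A an [make_influence()] influence matrix.
#' @param s the [structure_set()] (with derived shells, see
#'   [expand_structures()]).
#' @param options solver options from [plan_options()].
#' @return An object of class `rt_plan`: fluence, body-voxel dose, the
#'   attained/bound ledger (one row per objective), and provenance
#'   `"prioritized"`.
#' @export
solve_prioritized <- function(w, A, s, options = plan_options()) {
  stopifnot(inherits(w, "wishlist"), inherits(A, "influence_matrix"),
            inherits(s, "structure_set"))
  if (!isTRUE(w$resolved)) w <- resolve_limits(w)
  relax <- w$relaxation
  opts <- options
  mat <- A$A

  vols <- unique(c(vapply(w$constraints, `[[`, "", "volume"),
                   vapply(w$objectives, `[[`, "", "volume")))
  missing <- vols[!vols %in% names(s$masks)]
  if (length(missing))
    stop("wish-list volumes missing from the structure set: ",
         paste(missing, collapse = ", "),
         " (did you run expand_structures()?)")
  rows_of <- lapply(stats::setNames(vols, vols),
                    function(v) structure_rows(A, s, v))

  empty_vols <- names(rows_of)[vapply(rows_of, length, 0L) == 0L]
  if (length(empty_vols))
    warning("empty structure(s) referenced by the wish-list, skipped: ",
            paste(empty_vols, collapse = ", "))
  hard <- lapply(Filter(function(cn) !cn$volume %in% empty_vols,
                        w$constraints),
                 function(cn)
    con_linmax(rows_of[[cn$volume]], cn$limit,
               sprintf("constraint %s maximum %.4g Gy", cn$volume, cn$limit)))

  # warm start: uniform weight on beamlets with PTV coverage, scaled to 90%
  # of prescription mean, then shrunk to strict hard-constraint feasibility
  ptv_rows <- rows_of[["PTV"]]
  cov <- as.numeric(Matrix::colMeans(mat[ptv_rows, , drop = FALSE]))
  w0 <- as.numeric(cov > 0.25 * max(cov))
  d0 <- as.numeric(mat %*% w0)
  mp <- mean(d0[ptv_rows])
  if (mp > 0) w0 <- w0 * 0.9 * w$prescription$dose_gy / mp
  d0 <- as.numeric(mat %*% w0)
  shrink <- max(vapply(hard, function(cn)
    max(d0[cn$rows]) / cn$b, 0), 0)
  if (shrink > 0.95) w0 <- w0 * 0.95 / shrink

  state <- list(w = w0, d = as.numeric(mat %*% w0))
  cons <- hard
  nobj <- length(w$objectives)
  ledger <- data.frame(priority = numeric(nobj), volume = character(nobj),
                       kind = character(nobj), goal = numeric(nobj),
                       attained_pass1 = NA_real_, bound = NA_real_,
                       attained_pass2 = NA_real_, met_goal = NA,
                       stringsAsFactors = FALSE)
  obj_cons <- vector("list", nobj)  # bound constraint(s) per objective

  # incumbent value of objective i under the current dose
  incumbent_value <- function(i, d) {
    ob <- w$objectives[[i]]
    eval_objective(ob, d[rows_of[[ob$volume]]])
  }

  run_objective <- function(i, state, cons_other) {
    ob <- w$objectives[[i]]
    rows <- rows_of[[ob$volume]]
    if (ob$kind == "dose-volume") {
      T0 <- ob$params$threshold
      n_ex <- floor(ob$goal / 100 * length(rows))
      exempt_prev <- integer(0)
      res <- list(w = state$w, d = state$d)
      for (round in seq_len(opts$dv_rounds)) {
        ord <- order(res$d[rows], decreasing = TRUE)
        exempt <- sort(rows[ord[seq_len(n_ex)]])
        if (identical(exempt, exempt_prev) && round > 1) break
        exempt_prev <- exempt
        keep <- setdiff(rows, exempt)
        step_cons <- c(cons_other, if (length(keep)) list(
          con_linmax(keep, T0, sprintf("%s hot-voxel %g Gy",
                                       obj_label(ob), T0))))
        res <- solve_step(mat, res$w,
                          step_objective(ob, rows), step_cons, opts)
      }
      attained <- volume_at_dose(res$d[rows], T0)
      # a lexicographic step may never worsen its own objective or break
      # feasibility: the incumbent is feasible, so fall back to it when the
      # augmented-Lagrangian step drifted
      inc <- incumbent_value(i, state$d)
      fellback <- (!is.null(res$viol_true) &&
                     res$viol_true > 5 * opts$feas_tol) ||
        attained > inc + 1e-9
      if (fellback) { res <- state; attained <- inc }
      list(res = res, attained = attained, fellback = fellback,
           viol = res$viol_true %||% 0)
    } else {
      res <- solve_step(mat, state$w, step_objective(ob, rows), cons_other,
                        opts)
      attained <- eval_objective(ob, res$d[rows])
      inc <- incumbent_value(i, state$d)
      fellback <- res$viol_true > 5 * opts$feas_tol || attained > inc + 1e-9
      if (fellback) { res <- state; attained <- inc }
      list(res = res, attained = attained, fellback = fellback,
           viol = res$viol_true %||% 0)
    }
  }

  # dose-volume protection: voxels currently over threshold, plus an
  # allowance up to the bound fraction, stay exempt; all other organ voxels
  # are constrained to the threshold so later steps cannot push the
  # dose-volume value past its bound
  dv_protection <- function(ob, rows, d, bound) {
    T0 <- ob$params$threshold
    n_ex <- floor(bound / 100 * length(rows))
    ord <- order(d[rows], decreasing = TRUE)
    hot <- rows[d[rows] > T0 * (1 + opts$feas_tol)]
    exempt <- sort(union(rows[ord[seq_len(n_ex)]], hot))
    keep <- setdiff(rows, exempt)
    if (length(keep))
      list(con_linmax(keep, T0, sprintf("%s exempt-set", obj_label(ob))))
    else list()
  }

  # pass 1: priority order
  for (i in seq_len(nobj)) {
    ob <- w$objectives[[i]]
    if (ob$volume %in% empty_vols) {
      ledger$priority[i] <- ob$priority
      ledger$volume[i] <- ob$volume
      ledger$kind[i] <- ob$kind
      ledger$goal[i] <- ob$goal
      obj_cons[[i]] <- list()
      next
    }
    out <- run_objective(i, state, cons)
    state <- list(w = out$res$w, d = out$res$d)
    attained <- out$attained
    met <- attained <= ob$goal * (1 + opts$feas_tol)
    bound <- if (met) ob$goal else attained * (1 + relax)
    ledger$priority[i] <- ob$priority
    ledger$volume[i] <- ob$volume
    ledger$kind[i] <- ob$kind
    ledger$goal[i] <- ob$goal
    ledger$attained_pass1[i] <- attained
    ledger$bound[i] <- bound
    ledger$met_goal[i] <- met
    obj_cons[[i]] <- if (ob$kind == "dose-volume")
      dv_protection(ob, rows_of[[ob$volume]], state$d, bound)
    else {
      bc <- bound_constraint(ob, rows_of[[ob$volume]], bound, obj_label(ob))
      if (is.null(bc)) list() else list(bc)
    }
    cons <- c(cons, obj_cons[[i]])
    if (opts$verbose)
      message(sprintf("pass1 %-30s attained %.5g bound %.5g%s%s",
                      obj_label(ob), attained, bound,
                      if (met) " (goal met)" else "",
                      if (out$fellback) " [kept incumbent]" else ""))
  }

  # pass 2: re-minimize ("supersede") objectives that met their goals
  if (opts$two_pass) {
    for (i in which(!is.na(ledger$met_goal) & ledger$met_goal)) {
      ob <- w$objectives[[i]]
      cons_other <- c(hard, unlist(obj_cons[-i], recursive = FALSE))
      out <- run_objective(i, state, cons_other)
      state <- list(w = out$res$w, d = out$res$d)
      attained <- out$attained
      # keep the supersession, but never loosen past the goal
      bound <- min(ob$goal, attained * (1 + relax))
      ledger$attained_pass2[i] <- attained
      ledger$bound[i] <- bound
      obj_cons[[i]] <- if (ob$kind == "dose-volume")
        dv_protection(ob, rows_of[[ob$volume]], state$d, bound)
      else {
        bc <- bound_constraint(ob, rows_of[[ob$volume]], bound, obj_label(ob))
        if (is.null(bc)) list() else list(bc)
      }
      if (opts$verbose)
        message(sprintf("pass2 %-30s attained %.5g bound %.5g%s",
                        obj_label(ob), attained, bound,
                        if (out$fellback) " [kept incumbent]" else ""))
    }
  }

  # hard-constraint feasibility audit
  dfin <- state$d
  for (cn in hard) {
    v <- max(dfin[cn$rows]) / cn$b - 1
    if (v > 10 * opts$feas_tol)
      stop("infeasible: ", cn$label, " violated by ",
           sprintf("%.3g%%", 100 * v))
  }
  ledger$final <- vapply(seq_len(nobj), function(i) {
    rr <- rows_of[[w$objectives[[i]]$volume]]
    if (!length(rr)) NA_real_
    else eval_objective(w$objectives[[i]], dfin[rr])
  }, 0)

  new_plan(fluence = state$w, dose = dfin, A = A, s = s, w = w,
           provenance = "prioritized", ledger = ledger, options = opts)
}

new_plan <- function(fluence, dose, A, s, w, provenance, ledger, options) {
  structure(list(fluence = fluence, dose = dose, body_idx = A$body_idx,
                 grid = A$grid, provenance = provenance, ledger = ledger,
                 prescription_gy = w$prescription$dose_gy,
                 wishlist = w, options = options,
                 normalization = NULL),
            class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan> %s: %d beamlets, PTV-prescription %g Gy%s\n",
              x$provenance, length(x$fluence), x$prescription_gy,
              if (is.null(x$normalization)) ""
              else sprintf(" (normalized x%.4f)", x$normalization$factor)))
  if (!is.null(x$ledger) && nrow(x$ledger)) {
    cat("  objective ledger:\n")
    print(x$ledger, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Solve a weighted-sum baseline plan (template surrogate)
#'
#' Minimizes a fixed weighted sum of the wish-list's cost functions subject
#' to the same hard constraints and nonnegative fluence — a stand-in for
#' manual template-based planning, where relative objective weights are set
#' once rather than prioritized. Each cost is normalized by its goal so the
#' weights are comparable across kinds; maximum-dose objectives enter through
#' auxiliary variables and dose-volume objectives through a quadratic
#' over-threshold penalty.
#'
#' @param template_weights nonnegative numeric vector, one weight per
#'   wish-list objective row (in wish-list order), at least one positive.
#' @param w,A,s,options as in [solve_prioritized()].
#' @return An `rt_plan` with provenance `"baseline"`.
#' @export
solve_baseline <- function(template_weights, w, A, s,
                           options = plan_options()) {
  stopifnot(inherits(w, "wishlist"), inherits(A, "influence_matrix"),
            inherits(s, "structure_set"))
  if (!isTRUE(w$resolved)) w <- resolve_limits(w)
  opts <- options
  mat <- A$A
  nb <- ncol(mat)
  nobj <- length(w$objectives)
  tw <- as.numeric(template_weights)
  if (length(tw) != nobj)
    stop("need one weight per wish-list objective (", nobj, ")")
  if (any(tw < 0) || all(tw == 0))
    stop("weights must be nonnegative with at least one positive")

  vols <- unique(c(vapply(w$constraints, `[[`, "", "volume"),
                   vapply(w$objectives, `[[`, "", "volume")))
  rows_of <- lapply(stats::setNames(vols, vols),
                    function(v) structure_rows(A, s, v))
  empty_vols <- names(rows_of)[vapply(rows_of, length, 0L) == 0L]
  if (length(empty_vols))
    warning("empty structure(s) referenced by the wish-list, skipped: ",
            paste(empty_vols, collapse = ", "))
  hard <- lapply(Filter(function(cn) !cn$volume %in% empty_vols,
                        w$constraints),
                 function(cn)
    con_linmax(rows_of[[cn$volume]], cn$limit,
               sprintf("constraint %s maximum %.4g Gy", cn$volume, cn$limit)))

  act <- which(tw > 0 &
                 !vapply(w$objectives, `[[`, "", "volume") %in% empty_vols)
  terms <- lapply(act, function(i) {
    ob <- w$objectives[[i]]
    so <- step_objective(ob, rows_of[[ob$volume]])
    if (so$kind == "logltcp") {
      so$kind <- "ltcp_soft"
      so$params$goal <- ob$goal
    }
    # goal normalization; LTCP enters on its own (dimensionless) scale,
    # dose-volume is already normalized by its threshold
    gsc <- switch(ob$kind, "LTCP" = 1, "dose-volume" = 1, ob$goal)
    list(ob = ob, so = so, weight = tw[i], scale = gsc)
  })
  aux_terms <- which(vapply(terms, function(t) t$so$kind == "auxmax", TRUE))
  naux <- length(aux_terms)

  ptv_rows <- rows_of[["PTV"]]
  cov <- as.numeric(Matrix::colMeans(mat[ptv_rows, , drop = FALSE]))
  w0 <- as.numeric(cov > 0.25 * max(cov))
  d0 <- as.numeric(mat %*% w0)
  mp <- mean(d0[ptv_rows])
  if (mp > 0) w0 <- w0 * 0.9 * w$prescription$dose_gy / mp
  d0 <- as.numeric(mat %*% w0)
  shrink <- max(vapply(hard, function(cn) max(d0[cn$rows]) / cn$b, 0), 0)
  if (shrink > 0.95) w0 <- w0 * 0.95 / shrink
  d0 <- as.numeric(mat %*% w0)

  # composite objective over x = c(fluence, aux maxima)
  x0 <- c(w0, vapply(aux_terms, function(j)
    max(d0[terms[[j]]$so$rows]), 0))
  lower <- rep(0, nb + naux)
  cons <- hard
  # aux-max linkage constraints d[rows] <= t_j
  for (jj in seq_along(aux_terms)) {
    tm <- terms[[aux_terms[jj]]]
    cons <- c(cons, list(structure(
      con_linmax(tm$so$rows, 1, paste("aux", obj_label(tm$ob))),
      aux_slot = jj)))
  }

  lam <- NULL; rho <- opts$rho0
  nvox <- nrow(mat)
  evalpt <- function(x) {
    wv <- x[seq_len(nb)]
    taux <- if (naux) x[nb + seq_len(naux)] else numeric(0)
    d <- as.numeric(mat %*% wv)
    gd <- numeric(nvox)
    ga <- numeric(naux)
    fv <- 0
    for (jj in seq_along(terms)) {
      tm <- terms[[jj]]
      if (tm$so$kind == "auxmax") {
        slot <- match(jj, aux_terms)
        fv <- fv + tm$weight * taux[slot] / tm$scale
        ga[slot] <- ga[slot] + tm$weight / tm$scale
      } else {
        env <- new.env(parent = emptyenv()); env$gd <- numeric(nvox)
        fv <- fv + tm$weight * obj_value(tm$so, d) / tm$scale
        obj_add_grad(tm$so, d, env)
        gd <- gd + tm$weight * env$gd / tm$scale
      }
    }
    pen <- 0
    for (j in seq_along(cons)) {
      cn <- cons[[j]]
      slot <- attr(cn, "aux_slot")
      g <- if (is.null(slot)) con_g(cn, d)
           else (d[cn$rows] - taux[slot]) / cn$scale
      ge <- pmin(g, 0.5)  # Huberized hinge, as in solve_step
      y <- pmax(0, lam[[j]] + rho * ge)
      pen <- pen + (sum(y^2) - sum(lam[[j]]^2)) / (2 * rho) +
        sum(y * pmax(0, g - 0.5))
      gd[cn$rows] <- gd[cn$rows] + y / cn$scale
      if (!is.null(slot)) ga[slot] <- ga[slot] - sum(y) / cn$scale
    }
    gw <- as.numeric(Matrix::crossprod(mat, gd))
    list(val = fv + pen, grad = c(gw, ga), d = d)
  }

  # interior margin as in solve_step
  cons <- lapply(cons, function(cn) {
    if (is.null(attr(cn, "aux_slot")))
      cn$b <- cn$b * (1 - opts$constraint_margin)
    cn
  })
  lam <- lapply(cons, function(cn) numeric(length(cn$rows)))
  x <- x0
  # cache keyed on the point AND the multiplier state
  al_version <- 0L
  cache <- new.env(parent = emptyenv()); cache$x <- NULL
  fresh <- function(x) {
    if (!identical(cache$x, x) || !identical(cache$ver, al_version)) {
      cache$r <- evalpt(x); cache$x <- x; cache$ver <- al_version
    }
    cache$r
  }
  fn <- function(x) fresh(x)$val
  gr <- function(x) fresh(x)$grad
  tol_eff <- max(opts$feas_tol, 0.25 * opts$constraint_margin)
  viol_prev <- Inf
  for (outer in seq_len(opts$outer_max)) {
    val_prev <- Inf
    for (restart in 1:3) {
      fit <- stats::optim(x, fn, gr, method = "L-BFGS-B", lower = lower,
                          control = list(maxit = opts$inner_maxit,
                                         factr = 1e6))
      x <- fit$par
      if (fit$convergence == 52) {
        x <- pgd_polish(x, fn, gr, lower)
        fit$value <- fn(x)
      }
      if (val_prev - fit$value < 1e-5 * max(1, abs(fit$value))) break
      val_prev <- fit$value
    }
    r <- evalpt(x)
    d <- r$d
    taux <- if (naux) x[nb + seq_len(naux)] else numeric(0)
    gs <- lapply(seq_along(cons), function(j) {
      cn <- cons[[j]]; slot <- attr(cn, "aux_slot")
      if (is.null(slot)) con_g(cn, d)
      else (d[cn$rows] - taux[slot]) / cn$scale
    })
    viol <- max(0, unlist(gs, use.names = FALSE))
    if (viol <= tol_eff) break
    lam <- Map(function(l, g) pmax(0, l + rho * pmin(g, 0.5)), lam, gs)
    if (viol > 0.7 * viol_prev) rho <- min(rho * 4, 1e5)
    viol_prev <- viol
    al_version <- al_version + 1L
  }
  wv <- x[seq_len(nb)]
  dfin <- as.numeric(mat %*% wv)

  ledger <- data.frame(
    priority = vapply(w$objectives, function(o) as.numeric(o$priority), 0),
    volume = vapply(w$objectives, `[[`, "", "volume"),
    kind = vapply(w$objectives, `[[`, "", "kind"),
    goal = vapply(w$objectives, function(o) as.numeric(o$goal), 0),
    weight = tw,
    final = vapply(w$objectives, function(o) {
      rr <- rows_of[[o$volume]]
      if (!length(rr)) NA_real_ else eval_objective(o, dfin[rr])
    }, 0),
    stringsAsFactors = FALSE)

  new_plan(fluence = wv, dose = dfin, A = A, s = s, w = w,
           provenance = "baseline", ledger = ledger, options = opts)
}

#' Verify a plan against its wish-list
#'
#' Recomputes the dose from the stored fluence, re-evaluates every hard
#' constraint and every objective with the cost-function module (the same
#' code path the optimizer's ledger uses), and reports attained values
#' against limits/bounds.
#'
#' @param p an `rt_plan`.
#' @param w the wish-list (resolved automatically).
#' @param A the influence matrix the plan was computed with.
#' @param s the structure set.
#' @param tol relative tolerance for pass/fail, default `1e-4`.
#' @return data.frame with columns `item`, `volume`, `kind`, `attained`,
#'   `limit`, `pass`.
#' @export
verify_plan <- function(p, w, A, s, tol = 1e-4) {
  stopifnot(inherits(p, "rt_plan"), inherits(w, "wishlist"))
  if (!isTRUE(w$resolved)) w <- resolve_limits(w)
  d <- influence_dose(A, p$fluence)
  rows <- list()
  for (cn in w$constraints) {
    dr <- d[structure_rows(A, s, cn$volume)]
    if (!length(dr)) next
    att <- max_dose(dr)
    rows[[length(rows) + 1L]] <- data.frame(
      item = "constraint", volume = cn$volume, kind = "maximum",
      attained = att, limit = as.numeric(cn$limit),
      pass = att <= cn$limit * (1 + tol), stringsAsFactors = FALSE)
  }
  led <- p$ledger
  for (i in seq_along(w$objectives)) {
    ob <- w$objectives[[i]]
    dr <- d[structure_rows(A, s, ob$volume)]
    if (!length(dr)) next
    att <- eval_objective(ob, dr)
    lim <- if (!is.null(led$bound)) led$bound[i] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      item = "objective", volume = ob$volume, kind = ob$kind,
      attained = att, limit = lim,
      pass = is.na(lim) | att <= lim * (1 + tol) + 1e-9,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
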