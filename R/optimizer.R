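#' Solver configuration
#'
#' @param tol relative equality-feasibility tolerance (scaled by
#'   `1 + max |b|`)
#' @param max_iter maximum interior-point iterations per frame
#' @param max_failed_fraction fraction of failed frames above which a trial
#'   is flagged unusable
#' @return list of class `solver_config`
#' @export
solver_config <- function(tol = 1e-8, max_iter = 200,
                          max_failed_fraction = 0.2) {
  structure(list(tol = tol, max_iter = max_iter,
                 max_failed_fraction = max_failed_fraction),
            class = "solver_config")
}

# Primal-dual interior-point solve of
#   min sum_i c_i y_i^3   s.t.  At y = bt,  0 <= y <= u.
# Perturbed KKT system with slack duals zl, zu for the two bounds; the
# Newton step eliminates the slacks against a diagonal D = 6 c y + zl/y +
# zu/(u-y), leaving a p x p Schur solve per iteration. Fraction-to-boundary
# steps keep iterates strictly inside the box while the solution itself may
# sit on a bound (a reduced muscle set often pins antagonists at zero).
# Long-step path following: mu is reduced from the current complementarity
# gap each iteration.
solve_box_eq <- function(cc, u, At, bt, cfg, warm = NULL) {
  n <- length(cc)
  p <- nrow(At)
  if (p == 0) {
    return(list(y = numeric(n), lambda = numeric(0), ok = TRUE,
                primal_residual = 0))
  }
  tol_abs <- cfg$tol * (1 + max(abs(bt)))
  y <- if (!is.null(warm$y) && length(warm$y) == n) warm$y else pmin(u * 0.5, 50)
  y <- pmin(pmax(y, 1e-3 * pmin(u, 1)), u * (1 - 1e-6))
  nu <- if (!is.null(warm$lambda) && length(warm$lambda) == p) {
    warm$lambda
  } else numeric(p)
  zl <- pmax(1 / y, 1e-4)
  zu <- pmax(1 / (u - y), 1e-4)
  Att <- t(At)
  ok <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    r_d <- 3 * cc * y^2 + as.numeric(Att %*% nu) - zl + zu
    r_p <- as.numeric(At %*% y) - bt
    gap <- (sum(zl * y) + sum(zu * (u - y))) / (2 * n)
    if (max(abs(r_p)) <= tol_abs && max(abs(r_d)) <= 1e3 * tol_abs &&
        gap <= max(1e-10, tol_abs)) { ok <- TRUE; break }
    mu <- 0.2 * gap
    D <- 6 * cc * y + zl / y + zu / (u - y)
    rt <- 3 * cc * y^2 + as.numeric(Att %*% nu) - mu / y + mu / (u - y)
    Di <- 1 / D
    S <- At %*% (Di * Att)
    dnu <- tryCatch(solve(S, r_p - as.numeric(At %*% (Di * rt))),
                    error = function(e) NULL)
    if (is.null(dnu)) break
    dy <- -Di * (rt + as.numeric(Att %*% dnu))
    dzl <- mu / y - zl - (zl / y) * dy
    dzu <- mu / (u - y) - zu + (zu / (u - y)) * dy
    ap <- 1
    neg <- dy < 0
    if (any(neg)) ap <- min(ap, 0.995 * min(-y[neg] / dy[neg]))
    pos <- dy > 0
    if (any(pos)) ap <- min(ap, 0.995 * min((u[pos] - y[pos]) / dy[pos]))
    ad <- 1
    nl <- dzl < 0
    if (any(nl)) ad <- min(ad, 0.995 * min(-zl[nl] / dzl[nl]))
    nu_ <- dzu < 0
    if (any(nu_)) ad <- min(ad, 0.995 * min(-zu[nu_] / dzu[nu_]))
    y <- y + ap * dy
    nu <- nu + ad * dnu
    zl <- pmax(zl + ad * dzl, 1e-300)
    zu <- pmax(zu + ad * dzu, 1e-300)
  }
  list(y = y, lambda = nu, ok = ok,
       primal_residual = max(abs(At %*% y - bt)))
}

#' Solve one frame of the equilibrium system by static optimization
#'
#' Minimizes the sum of cubed muscle and ligament stresses,
#' \eqn{J = \sum_i (F_i/F_{max,i})^3 + \sum_j (L_j/L_{max,j})^3},
#' over nonnegative, bounded muscle/ligament (and patellar tendon) forces
#' and unbounded joint reactions, subject to the frame's equilibrium
#' equations. The costless unconstrained reaction columns are eliminated
#' analytically (QR null-space projection), and the reduced smooth convex
#' problem is solved by a primal-dual interior-point method. An infeasible
#' frame yields `converged = FALSE` rather than an error.
#'
#' @param system an `equilibrium_system` from [assemble_system()] (or a
#'   hand-built list with `A`, `b`, `column_map`)
#' @param config a [solver_config()]
#' @param pt_upper upper bound for the patellar tendon force (N); default is
#'   the rho-weighted quadriceps capacity plus slack
#' @param warm optional warm start (`y`, `lambda`) from a neighbouring frame
#' @return list of class `force_solution`: `forces` (named, bounded
#'   unknowns), `reactions` (named list of 3-vectors), `x` (full column
#'   vector), `cost`, `converged`, `residual`, `warm` (state for
#'   warm-starting the next frame)
#' @export
solve_frame <- function(system, config = solver_config(), pt_upper = NULL,
                        warm = NULL) {
  cm <- system$column_map
  bounded <- which(cm$type %in% c("muscle", "pt", "ligament"))
  free <- which(cm$type == "reaction")
  A <- system$A; b <- as.numeric(system$b)
  Af <- A[, bounded, drop = FALSE]

  u <- cm$f_max[bounded]
  cc <- ifelse(is.na(u), 0, 1 / ifelse(is.na(u), 1, u)^3)
  if (any(is.na(u))) {   # patellar tendon: costless, generous bound
    if (is.null(pt_upper)) {
      qsum <- sum(cm$f_max[cm$type == "muscle" & cm$group %in% "quadriceps"],
                  na.rm = TRUE)
      pt_upper <- max(1.5 * qsum, 2 * max(cm$f_max, na.rm = TRUE), 1000)
    }
    u[is.na(u)] <- pt_upper
  }

  if (length(free)) {
    Ar <- A[, free, drop = FALSE]
    qrr <- qr(Ar)
    r <- qrr$rank
    if (r < nrow(A)) {
      Q <- qr.Q(qrr, complete = TRUE)
      U2 <- Q[, (r + 1):nrow(A), drop = FALSE]
      At <- crossprod(U2, Af)
      bt <- as.numeric(crossprod(U2, b))
    } else {
      At <- matrix(0, 0, length(bounded)); bt <- numeric(0)
    }
  } else {
    At <- Af; bt <- b
  }

  sol <- solve_box_eq(cc, u, At, bt, config, warm = warm)
  y <- sol$y
  x <- numeric(ncol(A))
  x[bounded] <- y
  if (length(free)) {
    # minimum-norm reactions: the split of mediolateral shear between the
    # two tibiofemoral contact points is statically indeterminate (the
    # reaction block is rank-deficient along the contact line); the
    # pseudo-inverse resolves it with the smallest contact forces
    rres <- b - as.numeric(Af %*% y)
    sv <- svd(A[, free, drop = FALSE])
    pos <- sv$d > 1e-10 * sv$d[1]
    x[free] <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rres)) / sv$d[pos])
  }
  names(x) <- cm$name
  res <- residual(system, x)
  converged <- sol$ok && res <= 1e-6 * (1 + max(abs(b)))
  cost <- sum(cc * y^3)
  reactions <- list()
  for (rn in c("R_ankle", "R_med_tfj", "R_lat_tfj", "R_hip", "R_pfj")) {
    idx <- which(cm$name %in% paste0(rn, "_", c("x", "y", "z")))
    if (length(idx) == 3) reactions[[rn]] <- unname(x[idx])
  }
  structure(list(forces = x[bounded], reactions = reactions, x = x,
                 cost = cost, converged = converged, residual = res,
                 warm = list(y = y, lambda = sol$lambda)),
            class = "force_solution")
}

#' @export
print.force_solution <- function(x, ...) {
  cat("<force_solution>", if (x$converged) "converged," else "NOT converged,",
      "cost =", signif(x$cost, 5), ", residual =", signif(x$residual, 3), "\n")
  invisible(x)
}

#' Solve every frame of a trial
#'
#' Frames are solved in order, each warm-started from the previous frame's
#' solution; a frame that cannot be solved is flagged, not fatal (and does
#' not contaminate the next frame's warm start). The trial as a whole
#' is flagged unusable when the failed-frame fraction exceeds the
#' configured limit, mirroring how trials without a satisfactory solution
#' are omitted from downstream analysis.
#'
#' @param systems list of `equilibrium_system`, one per frame
#' @param config a [solver_config()]
#' @return list of class `trial_solution`: `solutions` (per frame),
#'   `converged` (logical vector), `n_failed`, `usable`
#' @export
solve_trial <- function(systems, config = solver_config()) {
  if (!length(systems)) stop("need at least one frame")
  sols <- vector("list", length(systems))
  warm <- NULL
  for (i in seq_along(systems)) {
    sols[[i]] <- tryCatch(solve_frame(systems[[i]], config, warm = warm),
                          error = function(e) {
                            structure(list(forces = NULL, reactions = NULL,
                                           x = NULL, cost = NA_real_,
                                           converged = FALSE,
                                           residual = NA_real_,
                                           error = conditionMessage(e)),
                                      class = "force_solution")
                          })
    if (isTRUE(sols[[i]]$converged)) warm <- sols[[i]]$warm
  }
  conv <- vapply(sols, `[[`, logical(1), "converged")
  n_failed <- sum(!conv)
  structure(list(solutions = sols, converged = conv, n_failed = n_failed,
                 usable = n_failed <= config$max_failed_fraction * length(sols)),
            class = "trial_solution")
}
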