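# Interior-point solver for the entropic flux balance problem.
#
# The full problem has unidirectional fluxes vf, vr >= 0 with entropy terms
# g * (vf log vf + vr log vr). For fixed net flux v = vf - vr the inner
# minimum has the closed form vf * vr = exp(-2) (sum the two stationarity
# conditions; every other term enters vf and vr with opposite signs), so with
# r = sqrt(v^2 + 4 exp(-2)):
#   vf = (r + v) / 2,  vr = (r - v) / 2
#   F(v)  = g (vf log vf + vr log vr)       (strictly convex, smooth)
#   F'(v) = (g / 2) log(vf / vr)
#   F''(v) = g / r
# That reduces the problem to a smooth strictly convex program in the net
# fluxes and exchange fluxes x = (v, w):
#   min  sum_i F_i(v_i) + ce.x + 0.5 sum_k H_k (x_k - h_k)^2
#   s.t. A x = b,  C x <= d,  l <= x <= u
# solved by a primal-dual interior-point method: coupling rows are folded in
# as equality rows with nonnegative slack variables, bound multipliers are
# kept explicit, and the barrier parameter tracks the average complementarity
# gap. Duals: y (mass balance / chemical potentials), y_C (couplings,
# recovered from the slack-bound multipliers), z_l, z_u (box). The
# nonnegativity duals of the unidirectional formulation are identically zero
# because the entropy terms keep vf, vr strictly positive.

FOUR_EXP_M2 <- 4 * exp(-2)

# entropic value/gradient/hessian of the reduced per-reaction term
ent_split <- function(v) {
  r <- sqrt(v^2 + FOUR_EXP_M2)
  list(vf = (r + v) / 2, vr = (r - v) / 2, r = r)
}

ent_value <- function(v, g) {
  s <- ent_split(v)
  g * (s$vf * log(s$vf) + s$vr * log(s$vr))
}

ent_grad <- function(v, g) {
  s <- ent_split(v)
  (g / 2) * log(s$vf / s$vr)
}

ent_hess <- function(v, g) {
  g / sqrt(v^2 + FOUR_EXP_M2)
}

#' Solver settings for the entropic interior-point method
#'
#' @param feasibility_tol maximum allowed infinity-norm of the mass-balance
#'   residual in accepted solutions.
#' @param stationarity_tol maximum allowed stationarity residual.
#' @param mu_min final barrier parameter (controls complementarity slack).
#' @param max_iter maximum interior-point iterations.
#' @return a list of solver settings.
#' @export
solver_control <- function(feasibility_tol = 1e-8, stationarity_tol = 1e-6,
                           mu_min = 1e-11, max_iter = 250) {
  list(feasibility_tol = feasibility_tol,
       stationarity_tol = stationarity_tol,
       mu_min = mu_min, max_iter = max_iter)
}

# robust dense solve: LAPACK QR, no hard failure on poor conditioning
solve_kkt <- function(M, rhs) {
  out <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (!is.null(out)) return(out)
  qr_m <- qr(M, LAPACK = TRUE)
  tryCatch(qr.coef(qr_m, rhs), error = function(e) NULL)
}

# Core solve over x with objective: entropic on `entropic` components
# (weight g), linear ce, diagonal quadratic H about h; A x = b, C x <= d,
# lb <= x <= ub. Returns x, duals (y, y_C, z_lower, z_upper), status.
barrier_solve <- function(A, b, lb, ub, entropic, g, ce, h, Hd,
                          C = NULL, d = numeric(), control = solver_control(),
                          x_start = NULL, diagnose_infeasible = TRUE,
                          polish = TRUE) {
  n0 <- ncol(A)
  A <- as.matrix(A)
  has_C <- !is.null(C) && nrow(C) > 0

  # fold coupling rows in as equalities with slack variables s in [0, Inf)
  if (has_C) {
    k <- nrow(C)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(as.matrix(C), diag(1, k)))
    b <- c(b, d)
    lb <- c(lb, rep(0, k))
    ub <- c(ub, rep(Inf, k))
    entropic <- c(entropic, rep(FALSE, k))
    g <- c(g, rep(2, k))
    ce <- c(ce, rep(0, k))
    h <- c(h, rep(0, k))
    Hd <- c(Hd, rep(0, k))
    if (!is.null(x_start)) x_start <- c(x_start, rep(NA_real_, k))
  } else {
    k <- 0L
  }
  n <- ncol(A)
  m <- nrow(A)

  obj_value <- function(xfull) {
    sum(ent_value(xfull[entropic], g[entropic])) +
      sum(ce * xfull) + 0.5 * sum(Hd * (xfull - h)^2)
  }

  # eliminate fixed variables (lb == ub)
  fixed <- is.finite(lb) & is.finite(ub) & abs(ub - lb) < 1e-12
  xfix <- ifelse(fixed, (lb + ub) / 2, 0)
  free <- !fixed
  nf <- sum(free)
  b_red_full <- b - as.vector(A %*% (xfix * fixed))

  finish_infeasible <- function(primal_resid) {
    if (diagnose_infeasible) {
      diag_res <- elastic_feasibility(A, b, lb, ub, control = control)
      if (diag_res$infeasible) {
        return(list(x = rep(NA_real_, n0), y = rep(NA_real_, m - k),
                    y_C = rep(NA_real_, k),
                    z_lower = rep(NA_real_, n0), z_upper = rep(NA_real_, n0),
                    status = "infeasible", objective = NA_real_,
                    primal_residual = diag_res$violation,
                    infeasibility_hint = diag_res$hint))
      }
    }
    list(x = rep(NA_real_, n0), y = rep(NA_real_, m - k),
         y_C = rep(NA_real_, k),
         z_lower = rep(NA_real_, n0), z_upper = rep(NA_real_, n0),
         status = "numerical_failure", objective = NA_real_,
         primal_residual = primal_resid)
  }

  if (nf == 0L) {
    feas <- max(abs(b_red_full))
    if (feas > sqrt(control$feasibility_tol)) {
      return(finish_infeasible(feas))
    }
    return(list(x = xfix[seq_len(n0)], y = rep(0, m - k), y_C = rep(0, k),
                z_lower = rep(0, n0), z_upper = rep(0, n0),
                status = "optimal", objective = obj_value(xfix),
                primal_residual = feas))
  }

  Af_full <- A[, free, drop = FALSE]
  # conserved moieties make mass-balance rows linearly dependent; keep an
  # independent subset (duals of dropped rows gauge to zero) and check the
  # dropped rows against the final iterate
  qrA <- qr(t(Af_full))
  keep_rows <- sort(qrA$pivot[seq_len(qrA$rank)])
  Af <- Af_full[keep_rows, , drop = FALSE]
  b_red <- b_red_full[keep_rows]
  mr <- length(keep_rows)

  lbf <- lb[free]; ubf <- ub[free]
  entf <- entropic[free]; gf <- g[free]; cef <- ce[free]
  hf <- h[free]; Hf <- Hd[free]
  lo_fin <- is.finite(lbf); up_fin <- is.finite(ubf)
  n_gap <- sum(lo_fin) + sum(up_fin)

  grad_f <- function(x) {
    gr <- cef + Hf * (x - hf)
    gr[entf] <- gr[entf] + ent_grad(x[entf], gf[entf])
    gr
  }
  hess_f <- function(x) {
    hd <- Hf + 1e-12
    hd[entf] <- hd[entf] + ent_hess(x[entf], gf[entf])
    hd
  }

  # strictly interior start
  interior_point <- function(xs = NULL) {
    margin <- pmin(1, ifelse(lo_fin & up_fin, 0.25 * (ubf - lbf), 1))
    x0 <- pmin(pmax(0, ifelse(lo_fin, lbf, -Inf) + margin),
               ifelse(up_fin, ubf, Inf) - margin)
    if (!is.null(xs)) {
      ok <- ifelse(lo_fin, xs > lbf + 1e-8, TRUE) &
        ifelse(up_fin, xs < ubf - 1e-8, TRUE) & is.finite(xs)
      x0[ok] <- xs[ok]
    }
    x0
  }
  x <- interior_point(if (!is.null(x_start)) x_start[free] else NULL)
  y <- rep(0, mr)
  zl <- ifelse(lo_fin, 1, 0)
  zu <- ifelse(up_fin, 1, 0)

  status <- "numerical_failure"
  mu <- 1
  for (it in seq_len(control$max_iter)) {
    sl <- x - lbf          # only meaningful where lo_fin
    su <- ubf - x
    r_d <- grad_f(x) - as.vector(crossprod(Af, y)) -
      ifelse(lo_fin, zl, 0) + ifelse(up_fin, zu, 0)
    r_p <- as.vector(Af %*% x) - b_red
    comp <- c(zl[lo_fin] * sl[lo_fin], zu[up_fin] * su[up_fin])
    gap <- if (length(comp)) mean(comp) else 0
    conv <- max(abs(r_d)) <= control$stationarity_tol / 2 &&
      max(abs(r_p)) <= control$feasibility_tol / 10 &&
      gap <= control$mu_min * 10
    if (conv) { status <- "optimal"; break }

    mu <- max(min(0.2 * gap, mu), control$mu_min)

    dgl <- ifelse(lo_fin, zl / pmax(sl, 1e-14), 0)
    dgu <- ifelse(up_fin, zu / pmax(su, 1e-14), 0)
    Hdg <- hess_f(x) + dgl + dgu
    rhs_x <- -r_d +
      ifelse(lo_fin, (mu - zl * sl) / pmax(sl, 1e-14), 0) -
      ifelse(up_fin, (mu - zu * su) / pmax(su, 1e-14), 0)
    KKT <- rbind(cbind(diag(Hdg, nf, nf), -t(Af)),
                 cbind(Af, matrix(0, mr, mr)))
    step <- solve_kkt(KKT, c(rhs_x, -r_p))
    if (is.null(step) || any(!is.finite(step))) break
    dx <- step[seq_len(nf)]
    dy <- step[nf + seq_len(mr)]
    dzl <- ifelse(lo_fin, (mu - zl * sl) / pmax(sl, 1e-14) - dgl * dx, 0)
    dzu <- ifelse(up_fin, (mu - zu * su) / pmax(su, 1e-14) + dgu * dx, 0)

    # fraction-to-boundary steps, primal and dual
    ftb <- function(v, dv, active) {
      sel <- active & dv < 0
      if (!any(sel)) 1 else min(1, 0.995 * min(-v[sel] / dv[sel]))
    }
    a_p <- min(ftb(sl, dx, lo_fin), ftb(su, -dx, up_fin))
    a_d <- min(ftb(zl, dzl, lo_fin), ftb(zu, dzu, up_fin))

    x <- x + a_p * dx
    y <- y + a_d * dy
    zl <- ifelse(lo_fin, zl + a_d * dzl, 0)
    zu <- ifelse(up_fin, zu + a_d * dzu, 0)
  }

  # Active-set polish: bounds with dominating multipliers are pinned and the
  # remaining (interior) problem re-solved; this removes the ill-conditioned
  # barrier terms and recovers machine-precision KKT residuals.
  if (polish) {
    sl <- x - lbf; su <- ubf - x
    comp <- c(zl[lo_fin] * sl[lo_fin], zu[up_fin] * su[up_fin])
    gap <- if (length(comp)) mean(comp) else 0
    if (gap <= 1e-8) {
      act_lo <- lo_fin & sl < 1e-6 & zl > 1e3 * pmax(sl, 1e-14)
      act_up <- up_fin & su < 1e-6 & zu > 1e3 * pmax(su, 1e-14)
      if (any(act_lo | act_up)) {
        lb2 <- lb; ub2 <- ub
        idx_free <- which(free)
        lb2[idx_free[act_lo]] <- lbf[act_lo]
        ub2[idx_free[act_lo]] <- lbf[act_lo]
        lb2[idx_free[act_up]] <- ubf[act_up]
        ub2[idx_free[act_up]] <- ubf[act_up]
        xs2 <- numeric(n)
        xs2[free] <- x
        xs2[fixed] <- xfix[fixed]
        res2 <- barrier_solve(A, b, lb2, ub2, entropic, g, ce, h, Hd,
                              control = control, x_start = xs2,
                              diagnose_infeasible = FALSE, polish = FALSE)
        if (res2$status == "optimal") {
          # adopt the polished primal point; duals are recovered below
          # against the original bounds
          x <- res2$x[free]
          status <- "optimal"
        }
      }
    }
  }

  # feasibility judged on the full (unreduced) mass-balance rows, so an
  # inconsistent dependent row is caught even though it was not iterated on
  r_pri <- as.vector(Af_full %*% x) - b_red_full
  primal_resid <- max(abs(r_pri))
  if (status == "optimal" &&
      primal_resid > control$feasibility_tol *
        max(1, max(abs(b_red_full), 1))) {
    status <- "numerical_failure"
  }
  if (status != "optimal") return(finish_infeasible(primal_resid))

  # Dual recovery by least squares: stationarity must hold exactly on the
  # variables whose bounds are inactive, which determines y; active bounds
  # (including fixed variables) absorb the remaining gradient gap as their
  # multipliers. This also fixes the gauge left open by dropped dependent
  # mass-balance rows.
  x_full <- numeric(n)
  x_full[free] <- x
  x_full[fixed] <- xfix[fixed]

  act_tol <- 1e-7
  at_lo <- is.finite(lb) & (x_full - lb) < act_tol * pmax(1, abs(lb))
  at_up <- is.finite(ub) & (ub - x_full) < act_tol * pmax(1, abs(ub))
  interior <- !(at_lo | at_up)

  gr_full <- ce + Hd * (x_full - h)
  gr_full[entropic] <- gr_full[entropic] +
    ent_grad(x_full[entropic], g[entropic])

  y_all <- numeric(m)
  y_all[keep_rows] <- y
  if (any(interior)) {
    A_int <- t(A[, interior, drop = FALSE])
    qr_int <- qr(A_int, LAPACK = TRUE)
    y_ls <- tryCatch(qr.coef(qr_int, gr_full[interior]),
                     error = function(e) NULL)
    if (!is.null(y_ls)) {
      y_ls[is.na(y_ls)] <- 0
      # accept only if it actually explains the interior gradients
      if (max(abs(as.vector(A_int %*% y_ls) - gr_full[interior])) <=
            max(control$stationarity_tol,
                max(abs(as.vector(A_int %*% y_all) -
                          gr_full[interior])))) {
        y_all <- y_ls
      }
    }
  }

  # rows not touched by any interior column are left unpriced by the least
  # squares; use them to move sign-violating gradient gaps of single-side
  # active bounds onto valid bound multipliers (the scarcity rent of capped
  # uptake chains sits on such rows)
  free_rows <- which(Matrix::rowSums(abs(A[, interior, drop = FALSE])) == 0)
  used <- rep(FALSE, m)
  tol0 <- control$stationarity_tol / 2
  for (pass in 1:3) {
    gap <- gr_full - as.vector(crossprod(A, y_all))
    vids <- which((at_up & !at_lo & gap > tol0) |
                    (at_lo & !at_up & gap < -tol0))
    if (!length(vids)) break
    moved <- FALSE
    for (i in vids) {
      gap_i <- gr_full[i] - sum(A[, i] * y_all)
      rs <- free_rows[!used[free_rows] & A[free_rows, i] != 0]
      if (!length(rs)) next
      r <- rs[1]
      y_all[r] <- y_all[r] + gap_i / A[r, i]
      used[r] <- TRUE
      moved <- TRUE
    }
    if (!moved) break
  }

  stat_gap <- gr_full - as.vector(crossprod(A, y_all))
  z_lo <- numeric(n); z_up <- numeric(n)
  z_lo[at_lo] <- pmax(stat_gap[at_lo], 0)
  z_up[at_up] <- pmax(-stat_gap[at_up], 0)

  # unfold coupling slacks: the slack lower-bound dual is y_C; its equality
  # row dual equals -y_C in this sign convention
  if (k > 0) {
    y_C <- pmax(z_lo[n0 + seq_len(k)], 0)
    y_mass <- y_all[seq_len(m - k)]
  } else {
    y_C <- numeric(0)
    y_mass <- y_all
  }

  list(x = x_full[seq_len(n0)], y = y_mass, y_C = y_C,
       z_lower = z_lo[seq_len(n0)], z_upper = z_up[seq_len(n0)],
       status = status, objective = obj_value(x_full),
       primal_residual = primal_resid)
}

# Elastic feasibility diagnosis: min 1's subject to A x + s+ - s- = b.
# A strictly positive optimum certifies infeasibility of the original
# constraint set; the largest slacks name the binding mass balances.
elastic_feasibility <- function(A, b, lb, ub, control = solver_control()) {
  n <- ncol(A); m <- nrow(A)
  Ae <- cbind(as.matrix(A), diag(1, m), diag(-1, m))
  big <- 1e6
  lbe <- c(lb, rep(0, 2 * m))
  ube <- c(ub, rep(big, 2 * m))
  ce <- c(rep(0, n), rep(1, 2 * m))
  res <- barrier_solve(Ae, b, lbe, ube,
                       entropic = rep(FALSE, n + 2 * m),
                       g = rep(2, n + 2 * m), ce = ce,
                       h = rep(0, n + 2 * m), Hd = rep(0, n + 2 * m),
                       control = modifyList(control, list(mu_min = 1e-9)),
                       diagnose_infeasible = FALSE)
  if (res$status != "optimal") {
    return(list(infeasible = FALSE, violation = NA_real_, hint = NULL))
  }
  slack <- abs(res$x[n + seq_len(2 * m)])
  total <- sum(slack)
  viol <- pmax(slack[seq_len(m)], slack[m + seq_len(m)])
  hint <- if (!is.null(rownames(A))) {
    rownames(A)[order(viol, decreasing = TRUE)][seq_len(min(5, m))]
  } else {
    order(viol, decreasing = TRUE)[seq_len(min(5, m))]
  }
  list(infeasible = is.finite(total) && total > 1e-5 * max(1, max(abs(b))),
       violation = total, hint = hint)
}
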