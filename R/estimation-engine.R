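# Marginal-likelihood machinery for the hierarchical model.
#
# The marginal likelihood integrates the conditional data likelihood over the
# per-subject random effects eta ~ N(0, Omega). The integral is approximated
# per subject by adaptive Gauss-Hermite quadrature centred at the conditional
# mode (Laplace approximation = 1 node). The inner mode search runs as a
# safeguarded Newton iteration vectorised across subjects; with warm starts
# between outer iterations it converges in a handful of steps.

# Gauss-Hermite nodes/weights (weight function exp(-z^2)) by Golub-Welsch.
gauss_hermite <- function(n) {
  if (n == 1) return(list(z = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(z = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Precompute per-observation dose lag matrices so concentration evaluation is
# one vectorised expression per exponential term.
prep_nlme <- function(dataset, model) {
  subs <- dataset$subjects
  obs <- dataset$obs[dataset$obs$mdv == 0, , drop = FALSE]
  if (nrow(obs) == 0) stop_input("dataset has no likelihood observations")
  subj_idx <- match(obs$id, subs$id)
  dlist <- split(dataset$doses[, c("time", "amt")], dataset$doses$id)
  maxD <- max(vapply(dlist, nrow, 1L), 1L)
  n_obs <- nrow(obs)
  dt <- matrix(Inf, n_obs, maxD)
  amt <- matrix(0, n_obs, maxD)
  for (i in seq_len(n_obs)) {
    dl <- dlist[[as.character(obs$id[i])]]
    if (is.null(dl)) next
    lag <- obs$time[i] - dl$time
    ok <- which(lag >= 0)
    if (length(ok)) {
      dt[i, seq_along(ok)] <- lag[ok]
      amt[i, seq_along(ok)] <- dl$amt[ok]
    }
  }
  list(obs = obs, subj_idx = subj_idx, dt = dt, amt = amt,
       covs = subs[, c("age", "body_weight", "sex", "csDMARD")],
       n_subj = nrow(subs), twocpt = is_twocpt(model$typical))
}

# concentrations for every likelihood observation given an n_subj x 5
# parameter matrix
conc_for_obs <- function(prep, P) {
  idx <- prep$subj_idx
  ka <- P[idx, "ka"]
  V <- P[idx, "VD"]
  if (!prep$twocpt) {
    ke <- P[idx, "CL"] / V
    close <- is.finite(ke) & abs(ka - ke) / ke < 1e-7
    if (any(close)) ke[close] <- ke[close] * (1 + 1e-6)
    coef <- ka / (V * (ka - ke))
    return(coef * rowSums(prep$amt * (exp(-ke * prep$dt) - exp(-ka * prep$dt))))
  }
  k10 <- P[idx, "CL"] / V
  k12 <- P[idx, "Q"] / V
  k21 <- P[idx, "Q"] / P[idx, "VP"]
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  sep <- pmax(1e-7 * ka, 1e-12)
  be[abs(al - be) < sep] <- be[abs(al - be) < sep] - sep[abs(al - be) < sep]
  ka[abs(ka - al) < sep] <- ka[abs(ka - al) < sep] * (1 + 1e-6)
  ka[abs(ka - be) < sep] <- ka[abs(ka - be) < sep] * (1 + 1e-6)
  A <- ka * (k21 - al) / (V * (ka - al) * (be - al))
  B <- ka * (k21 - be) / (V * (ka - be) * (al - be))
  Cc <- ka * (k21 - ka) / (V * (al - ka) * (be - ka))
  rowSums(prep$amt * (A * exp(-al * prep$dt) + B * exp(-be * prep$dt) +
                        Cc * exp(-ka * prep$dt)))
}

# per-subject conditional -log-likelihood given random-effect matrix etas
cond_nll_by_subject <- function(prep, P0, bsv_names, etas, sig_add, sig_prop) {
  P <- P0
  for (j in seq_along(bsv_names)) {
    nm <- bsv_names[j]
    P[, nm] <- P0[, nm] * exp(etas[, j])
  }
  f <- conc_for_obs(prep, P)
  sd <- sqrt(pmax(f^2 * sig_prop^2 + sig_add^2, 1e-20))
  nll <- -stats::dnorm(prep$obs$dv, f, sd, log = TRUE)
  nll[!is.finite(nll)] <- 1e8  # keep the objective finite off the feasible path
  out <- numeric(prep$n_subj)
  agg <- rowsum(nll, prep$subj_idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Vectorised safeguarded Newton for the penalised (joint) objective, all
# subjects simultaneously; k is the random-effect dimension.
inner_modes <- function(pen, eta0, k, max_iter = 40, tol = 1e-7) {
  eta <- eta0
  f0 <- pen(eta)
  h <- 1e-4
  for (iter in seq_len(max_iter)) {
    G <- matrix(0, nrow(eta), k)
    H <- array(0, c(nrow(eta), k, k))
    for (j in seq_len(k)) {
      ep <- em <- eta
      ep[, j] <- eta[, j] + h
      em[, j] <- eta[, j] - h
      fp <- pen(ep); fm <- pen(em)
      G[, j] <- (fp - fm) / (2 * h)
      H[, j, j] <- (fp + fm - 2 * f0) / h^2
    }
    if (k == 2) {
      epp <- epm <- emp <- emm <- eta
      epp[, 1] <- epp[, 1] + h; epp[, 2] <- epp[, 2] + h
      epm[, 1] <- epm[, 1] + h; epm[, 2] <- epm[, 2] - h
      emp[, 1] <- emp[, 1] - h; emp[, 2] <- emp[, 2] + h
      emm[, 1] <- emm[, 1] - h; emm[, 2] <- emm[, 2] - h
      H[, 1, 2] <- H[, 2, 1] <-
        (pen(epp) - pen(epm) - pen(emp) + pen(emm)) / (4 * h^2)
    } else if (k > 2) {
      for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
        epp <- epm <- emp <- emm <- eta
        epp[, a] <- epp[, a] + h; epp[, b] <- epp[, b] + h
        epm[, a] <- epm[, a] + h; epm[, b] <- epm[, b] - h
        emp[, a] <- emp[, a] - h; emp[, b] <- emp[, b] + h
        emm[, a] <- emm[, a] - h; emm[, b] <- emm[, b] - h
        H[, a, b] <- H[, b, a] <-
          (pen(epp) - pen(epm) - pen(emp) + pen(emm)) / (4 * h^2)
      }
    }
    step <- newton_step(G, H, k)
    if (max(abs(step)) < tol) break
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -2), 2)
    # per-subject step halving where the penalised objective would increase
    lam <- rep(1, nrow(eta))
    for (half in 1:12) {
      cand <- pmin(pmax(eta - step * lam, -30), 30)
      fc <- pen(cand)
      bad <- fc > f0 + 1e-10
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    moved <- fc <= f0 + 1e-10
    eta[moved, ] <- cand[moved, , drop = FALSE]
    f0[moved] <- fc[moved]
    if (max(abs(step * lam)[moved, , drop = FALSE], 0) < tol) break
  }
  # Fallback for subjects whose mode search stalled (vector Newton can stall
  # on hard conditionals): per-subject quasi-Newton from both the current
  # iterate and the origin, keeping the better mode.
  G <- matrix(0, nrow(eta), k)
  for (j in seq_len(k)) {
    ep <- em <- eta
    ep[, j] <- eta[, j] + h
    em[, j] <- eta[, j] - h
    G[, j] <- (pen(ep) - pen(em)) / (2 * h)
  }
  bad <- which(rowSums(abs(G)) > 0.05)
  for (i in bad) {
    pen_i <- function(ev) {
      et <- eta
      et[i, ] <- ev
      pen(et)[i]
    }
    best <- list(par = eta[i, ], objective = f0[i])
    for (start_pt in list(eta[i, ], rep(0, k))) {
      cand <- tryCatch(stats::nlminb(start_pt, pen_i), error = function(e) NULL)
      if (!is.null(cand) && is.finite(cand$objective) &&
          cand$objective < best$objective - 1e-10)
        best <- cand
    }
    eta[i, ] <- pmin(pmax(best$par, -30), 30)
    f0[i] <- best$objective
  }
  # Recompute the curvature at the mode with a larger step: second
  # differences at h = 1e-4 carry ~1e-5 relative roundoff from cancellation,
  # which is enough to corrupt the outer finite-difference gradients.
  hh <- 8e-3
  H <- array(0, c(nrow(eta), k, k))
  for (j in seq_len(k)) {
    ep <- em <- eta
    ep[, j] <- eta[, j] + hh
    em[, j] <- eta[, j] - hh
    H[, j, j] <- (pen(ep) + pen(em) - 2 * f0) / hh^2
  }
  if (k >= 2) for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    epp <- epm <- emp <- emm <- eta
    epp[, a] <- epp[, a] + hh; epp[, b] <- epp[, b] + hh
    epm[, a] <- epm[, a] + hh; epm[, b] <- epm[, b] - hh
    emp[, a] <- emp[, a] - hh; emp[, b] <- emp[, b] + hh
    emm[, a] <- emm[, a] - hh; emm[, b] <- emm[, b] - hh
    H[, a, b] <- H[, b, a] <-
      (pen(epp) - pen(epm) - pen(emp) + pen(emm)) / (4 * hh^2)
  }
  list(eta = eta, f = f0, H = regularise_H(H, k))
}

# Newton direction H^{-1} g per subject, with PD safeguarding
newton_step <- function(G, H, k) {
  n <- nrow(G)
  H <- regularise_H(H, k)
  if (k == 1) return(G / H[, 1, 1])
  if (k == 2) {
    det <- H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2
    s1 <- (H[, 2, 2] * G[, 1] - H[, 1, 2] * G[, 2]) / det
    s2 <- (H[, 1, 1] * G[, 2] - H[, 1, 2] * G[, 1]) / det
    return(cbind(s1, s2))
  }
  t(vapply(seq_len(n), function(i) solve(H[i, , ], G[i, ]), numeric(k)))
}

regularise_H <- function(H, k) {
  if (k == 1) {
    H[, 1, 1] <- pmax(H[, 1, 1], 1e-6)
    return(H)
  }
  if (k == 2) {
    tr <- H[, 1, 1] + H[, 2, 2]
    gap <- sqrt((H[, 1, 1] - H[, 2, 2])^2 + 4 * H[, 1, 2]^2)
    lmin <- (tr - gap) / 2
    ridge <- pmax(1e-6 - lmin, 0)
    H[, 1, 1] <- H[, 1, 1] + ridge
    H[, 2, 2] <- H[, 2, 2] + ridge
    return(H)
  }
  for (i in seq_len(dim(H)[1])) {
    lmin <- min(eigen(H[i, , ], symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 1e-6) H[i, , ] <- H[i, , ] + diag(1e-6 - lmin, k)
  }
  H
}

logdet_H <- function(H, k) {
  if (k == 1) return(log(H[, 1, 1]))
  if (k == 2) return(log(H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2))
  vapply(seq_len(dim(H)[1]), function(i)
    determinant(H[i, , ], logarithm = TRUE)$modulus[1], 0)
}

# Marginal -log-likelihood of the whole dataset for fully specified model
# values. `state` carries warm-start modes between calls.
marginal_nll <- function(prep, theta, bsv_omega, bsv_corr, effects,
                         sig_add, sig_prop, agq_nodes = NULL, state = NULL) {
  n <- prep$n_subj
  k <- length(bsv_omega)
  base <- c(CL = theta[["CL"]], VD = theta[["VD"]], ka = theta[["ka"]],
            Q = if ("Q" %in% names(theta)) theta[["Q"]] else NA_real_,
            VP = if ("VP" %in% names(theta)) theta[["VP"]] else NA_real_)
  P0 <- matrix(rep(base, each = n), n, 5, dimnames = list(NULL, names(base)))
  if (length(effects)) P0 <- P0 * covariate_factors(effects, prep$covs)
  if (k == 0)
    return(list(nll = sum(cond_nll_by_subject(prep, P0, character(0),
                                              matrix(0, n, 0), sig_add, sig_prop)),
                etas = matrix(0, n, 0), ipar = P0))
  bn <- names(bsv_omega)
  Om <- diag(bsv_omega, k) %*% (bsv_corr %||% diag(k)) %*% diag(bsv_omega, k)
  Oinv <- solve(Om)
  ld_Om <- determinant(Om, logarithm = TRUE)$modulus[1]
  pen <- function(etas) {
    etas <- pmin(pmax(etas, -30), 30)
    v <- cond_nll_by_subject(prep, P0, bn, etas, sig_add, sig_prop) +
      0.5 * rowSums((etas %*% Oinv) * etas)
    v[!is.finite(v)] <- 1e9
    v
  }
  eta0 <- if (!is.null(state) && !is.null(state$etas) &&
              all(dim(state$etas) == c(n, k))) state$etas else matrix(0, n, k)
  im <- inner_modes(pen, eta0, k)
  ld_H <- logdet_H(im$H, k)
  nodes <- agq_nodes %||% (if (k == 1) 9L else if (k == 2) 5L else 1L)
  if (nodes <= 1L || k > 2) {
    # Laplace: -ll_i = pen_i + 0.5 log|Omega| + 0.5 log|H_i|
    nll_i <- im$f + 0.5 * ld_Om + 0.5 * ld_H
  } else {
    gh <- gauss_hermite(nodes)
    const_prior <- 0.5 * (k * log(2 * pi) + ld_Om)
    if (k == 1) {
      s <- 1 / sqrt(im$H[, 1, 1])
      logs <- matrix(NA_real_, n, nodes)
      for (q in seq_len(nodes)) {
        etaq <- im$eta + sqrt(2) * s * gh$z[q]
        logs[, q] <- log(gh$w[q]) + gh$z[q]^2 - (pen(etaq) + const_prior)
      }
      m <- apply(logs, 1, max)
      nll_i <- -(0.5 * log(2) - 0.5 * ld_H + m + log(rowSums(exp(logs - m))))
    } else {
      # k == 2: tensor grid with per-subject Cholesky of H^{-1}
      a11 <- im$H[, 1, 1]; a12 <- im$H[, 1, 2]; a22 <- im$H[, 2, 2]
      # lower Cholesky L of H^{-1} via H = R'R, H^{-1} = R^{-1} R^{-T}
      r11 <- sqrt(a11); r12 <- a12 / r11
      r22 <- sqrt(pmax(a22 - r12^2, 1e-12))
      # columns of R^{-1}: [1/r11, -r12/(r11 r22); 0, 1/r22]
      qgrid <- expand.grid(q1 = seq_len(nodes), q2 = seq_len(nodes))
      logs <- matrix(NA_real_, n, nrow(qgrid))
      for (g in seq_len(nrow(qgrid))) {
        z1 <- gh$z[qgrid$q1[g]]; z2 <- gh$z[qgrid$q2[g]]
        d1 <- sqrt(2) * (z1 / r11 - z2 * r12 / (r11 * r22))
        d2 <- sqrt(2) * (z2 / r22)
        etaq <- im$eta + cbind(d1, d2)
        logs[, g] <- log(gh$w[qgrid$q1[g]]) + log(gh$w[qgrid$q2[g]]) +
          z1^2 + z2^2 - (pen(etaq) + const_prior)
      }
      m <- apply(logs, 1, max)
      nll_i <- -(log(2) - 0.5 * ld_H + m + log(rowSums(exp(logs - m))))
    }
  }
  if (!is.null(state) && all(is.finite(im$eta))) state$etas <- im$eta
  ipar <- P0
  for (j in seq_along(bn)) ipar[, bn[j]] <- P0[, bn[j]] * exp(im$eta[, j])
  list(nll = sum(nll_i), etas = im$eta, ipar = ipar)
}

# ---- free-parameter bookkeeping -------------------------------------------

# Build the free-parameter specification for a model: names, blocks and
# log/identity transforms. Fixed entries never enter the vector and are
# returned bit-identical in the output model.
build_pspec <- function(model) {
  th <- model$typical
  entries <- list()
  add <- function(name, block, value, trans = "log") {
    entries[[length(entries) + 1L]] <<- list(name = name, block = block,
                                             value = value, trans = trans)
  }
  add("CL", "theta", th$CL); add("VD", "theta", th$VD); add("ka", "theta", th$ka)
  if (is_twocpt(th)) { add("Q", "theta", th$Q); add("VP", "theta", th$VP) }
  for (nm in names(model$bsv)) add(paste0("omega_", nm), "omega", model$bsv[[nm]])
  ek <- model$error_model$kind
  if (ek %in% c("additive", "combined"))
    add("sigma_add", "sigma", model$error_model$sigma_add)
  if (ek %in% c("proportional", "combined"))
    add("sigma_prop", "sigma", model$error_model$sigma_prop)
  for (i in seq_along(model$covariate_effects)) {
    ef <- model$covariate_effects[[i]]
    add(sprintf("beta_%s_%s", ef$covariate, ef$parameter), "beta",
        ef$coefficient, trans = "identity")
  }
  fixed <- vapply(entries, function(e) e$name %in% model$fixed, TRUE)
  free <- entries[!fixed]
  if (!length(free)) stop_input("non-identifiable configuration: all parameters fixed")
  bad <- vapply(free, function(e) e$trans == "log" && e$value <= 0, TRUE)
  if (any(bad))
    stop_input("free parameter(s) need positive initial values: ",
               paste(vapply(free[bad], `[[`, "", "name"), collapse = ", "))
  list(entries = entries, free = free,
       start = vapply(free, function(e)
         if (e$trans == "log") log(e$value) else e$value, 0),
       free_names = vapply(free, `[[`, "", "name"))
}

# model with the free-parameter vector x substituted in
apply_pspec <- function(model, pspec, x) {
  vals <- stats::setNames(lapply(pspec$entries, `[[`, "value"),
                          vapply(pspec$entries, `[[`, "", "name"))
  for (i in seq_along(pspec$free)) {
    e <- pspec$free[[i]]
    vals[[e$name]] <- if (e$trans == "log") exp(x[i]) else x[i]
  }
  th <- model$typical
  new_typ <- pk_params(CL = vals$CL, VD = vals$VD, ka = vals$ka,
                       Q = vals$Q, VP = vals$VP)
  bsv <- model$bsv
  for (nm in names(bsv)) bsv[[nm]] <- vals[[paste0("omega_", nm)]]
  em <- model$error_model
  em$sigma_add <- vals$sigma_add %||% em$sigma_add
  em$sigma_prop <- vals$sigma_prop %||% em$sigma_prop
  effects <- model$covariate_effects
  for (i in seq_along(effects)) {
    nm <- sprintf("beta_%s_%s", effects[[i]]$covariate, effects[[i]]$parameter)
    effects[[i]]$coefficient <- vals[[nm]]
  }
  out <- model
  out$typical <- new_typ
  out$bsv <- bsv
  out$error_model <- em
  out$covariate_effects <- effects
  out
}

model_nll <- function(model, prep, agq_nodes = NULL, state = NULL) {
  th <- model$typical
  theta <- c(CL = th$CL, VD = th$VD, ka = th$ka)
  if (is_twocpt(th)) theta <- c(theta, Q = th$Q, VP = th$VP)
  marginal_nll(prep, theta, model$bsv, model$bsv_corr,
               model$covariate_effects, model$error_model$sigma_add,
               model$error_model$sigma_prop, agq_nodes, state)
}

#' Marginal -2 log-likelihood of a model on a dataset
#'
#' Evaluates the marginal (random-effects-integrated) deviance at the model's
#' stated parameter values, using adaptive Gauss-Hermite quadrature
#' (`agq_nodes` per random-effect dimension; 1 node is the Laplace
#' approximation).
#'
#' @param model a [population_model()]
#' @param dataset a [study_dataset()]
#' @param agq_nodes quadrature nodes per dimension (default: 9 for one
#'   random effect, 5x5 for two, Laplace beyond)
#' @return the -2 log-likelihood (a single number)
#' @export
minus2ll <- function(model, dataset, agq_nodes = NULL) {
  prep <- prep_nlme(dataset, model)
  2 * model_nll(model, prep, agq_nodes)$nll
}
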