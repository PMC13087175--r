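# Multicomponent equilibrium engine: simultaneously closes the Fe mass
# balance, the Donnan charge balance of each organic phase, and the
# ferrihydrite saturation condition, distributing total Fe over
# Fe', FeDOM, FeSid, FePOM and authFeOH.
#
# Unknowns are log-transformed ([Fe3+], chi_DOM, chi_POM) to enforce
# positivity. The default path is a damped Newton iteration with a
# finite-difference Jacobian; precipitation is handled as a complementarity
# branch (solve, check saturation, cap, re-solve). A nested bracketing
# bisection solver doubles as an independent oracle and as an automatic
# fallback.

#' Define a speciation problem
#'
#' @param total_fe Total Fe boundary condition, mol L-1 (observed dissolved
#'   Fe for pathway sets without POM; dissolved + labile particulate Fe when
#'   the POM pathway is active).
#' @param ph_total pH on the total scale (converted internally to the free
#'   scale; the proton activity is an imposed condition, not a solved
#'   unknown).
#' @param temp_c Temperature, Celsius.
#' @param salinity Practical salinity.
#' @param dom,pom `fe_nica_phase` objects or `NULL`; phases with zero mass
#'   bind no iron.
#' @param siderophore An `fe_ligand` or `NULL`.
#' @param allow_mineral Permit authigenic Fe oxyhydroxide precipitation when
#'   the Fe3+ activity exceeds the solubility cap.
#' @param thermo An `fe_thermo` dataset.
#' @return A list of class `fe_problem`.
#' @export
speciation_problem <- function(total_fe, ph_total, temp_c, salinity,
                               dom = NULL, pom = NULL, siderophore = NULL,
                               allow_mineral = FALSE, thermo = fe_thermo()) {
  if (total_fe < 0) abort("`total_fe` must be non-negative.")
  structure(
    list(total_fe = total_fe, ph_total = ph_total, temp_c = temp_c,
         salinity = salinity, dom = dom, pom = pom,
         siderophore = siderophore, allow_mineral = allow_mineral,
         thermo = thermo),
    class = "fe_problem"
  )
}

# Precompute everything that does not depend on the unknowns.
build_context <- function(pr) {
  sw <- seawater_composition(pr$salinity, pr$temp_c)
  I <- sw$ionic_strength
  gam <- gamma_table(I, pr$temp_c, pr$thermo$activity_model)
  ph_free <- convert_ph(pr$ph_total, "total", "free", pr$salinity, pr$temp_c)
  aH <- 10^(-ph_free)
  cH <- aH / gam["1"]
  alpha_fp <- fe_prime_alpha(ph_free, pr$temp_c, pr$salinity, pr$thermo)
  ctx <- list(
    sw = sw, I = I, gam = gam, ph_free = ph_free, aH = aH, cH = unname(cH),
    alpha_fp = alpha_fp, total_fe = pr$total_fe,
    allow_mineral = pr$allow_mineral
  )
  if (!is.null(pr$siderophore) && pr$siderophore$total > 0) {
    ctx$sid_total <- pr$siderophore$total
    ctx$sid_alpha <- sid_alpha(pr$siderophore$constants, ph_free, sw)
    ctx$sid_bfe <- 10^pr$siderophore$constants$logb_fe
  }
  for (nm in c("dom", "pom")) {
    ph <- pr[[nm]]
    if (!is.null(ph) && ph$mass > 0) {
      ctx[[nm]] <- list(
        phase = ph, mass = ph$mass,
        vd = donnan_volume(ph$donnan_b, I),
        bind_conc = c(h = unname(cH), mg = unname(sw$conc["mg"]),
                      ca = unname(sw$conc["ca"]), fe = 0),
        qtot = sum(vapply(ph$groups, `[[`, numeric(1), "qmax"))
      )
    }
  }
  if (pr$allow_mineral) {
    logks <- mineral_logks(pr$thermo, pr$temp_c + 273.15)
    ctx$fe3_cap <- 10^(logks - 3 * ph_free) / unname(gam["3"])
    ctx$logks <- logks
  }
  ctx
}

# bound Fe (mol/L) and gel charge residual for a phase at given fe3, chi
phase_eval <- function(pc, fe3, chi, ctx) {
  bc <- pc$bind_conc
  bc["fe"] <- fe3
  local <- bc * chi^.BIND_Z
  fe_bound <- 0
  zb <- 0
  for (g in pc$phase$groups) {
    b <- nica_bound_group(g, local)
    fe_bound <- fe_bound + b["fe"]
    zb <- zb + sum(.BIND_Z * b[names(.BIND_Z)], na.rm = TRUE)
  }
  q <- -pc$qtot + zb
  charge <- q + pc$vd * sum(ctx$sw$charge * ctx$sw$conc *
                              (chi^ctx$sw$charge - 1))
  list(fe_bound = unname(fe_bound) * pc$mass, charge = charge)
}

sid_bound <- function(ctx, fe3) {
  if (is.null(ctx$sid_total)) return(0)
  ctx$sid_bfe * fe3 * ctx$sid_total / (ctx$sid_alpha + ctx$sid_bfe * fe3)
}

# residual vector at unknowns u = log(c(fe3, chi_dom, chi_pom)) (active set)
eq_residual <- function(u, ctx, fe3_fixed = NULL) {
  i <- 1
  if (is.null(fe3_fixed)) {
    fe3 <- exp(u[i]); i <- i + 1
  } else {
    fe3 <- fe3_fixed
  }
  res <- numeric(0)
  dissolved <- ctx$alpha_fp * fe3 + sid_bound(ctx, fe3)
  charge <- c(dom = NA_real_, pom = NA_real_)
  for (nm in c("dom", "pom")) {
    if (!is.null(ctx[[nm]])) {
      chi <- exp(u[i]); i <- i + 1
      pe <- phase_eval(ctx[[nm]], fe3, chi, ctx)
      dissolved <- dissolved + pe$fe_bound
      charge[nm] <- pe$charge / (ctx[[nm]]$qtot + 2 * ctx[[nm]]$vd * ctx$I)
    }
  }
  if (is.null(fe3_fixed)) res <- dissolved / ctx$total_fe - 1
  c(res, charge[!is.na(charge)])
}

newton_solve <- function(u0, fn, tol = 1e-10, maxit = 60) {
  u <- u0
  f <- fn(u)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) {
      return(list(u = u, f = f, iterations = it - 1, converged = TRUE))
    }
    n <- length(u)
    J <- matrix(0, n, n)
    h <- 1e-7
    for (j in seq_len(n)) {
      up <- u
      up[j] <- up[j] + h
      J[, j] <- (fn(up) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(u = u, f = f, iterations = it, converged = FALSE))
    }
    lam <- 1
    ok <- FALSE
    for (k in 1:50) {
      un <- u + lam * step
      fn_new <- fn(un)
      if (all(is.finite(fn_new)) && max(abs(fn_new)) < max(abs(f))) {
        u <- un
        f <- fn_new
        ok <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!ok) return(list(u = u, f = f, iterations = it, converged = FALSE))
  }
  list(u = u, f = f, converged = max(abs(f)) < tol, iterations = maxit)
}

# root of a monotone scalar residual with geometric bracket widening
bracket_root <- function(fn, lo, hi, widen = 3, tol = 1e-13) {
  flo <- fn(lo)
  fhi <- fn(hi)
  k <- 0
  while (flo * fhi > 0 && k < widen) {
    lo <- lo - (hi - lo)
    hi <- hi + (hi - lo)
    flo <- fn(lo)
    fhi <- fn(hi)
    k <- k + 1
  }
  if (flo * fhi > 0) abort("bracketing failed: no sign change after widening.")
  uniroot(fn, c(lo, hi), f.lower = flo, f.upper = fhi, tol = tol)$root
}

solve_chis_at_fe3 <- function(ctx, fe3) {
  out <- c(dom = 1, pom = 1)
  for (nm in c("dom", "pom")) {
    if (!is.null(ctx[[nm]])) {
      pc <- ctx[[nm]]
      out[nm] <- exp(bracket_root(function(lchi)
        phase_eval(pc, fe3, exp(lchi), ctx)$charge, -14, 14))
    }
  }
  out
}

mass_balance_fe3 <- function(ctx, chis) {
  total <- ctx$total_fe
  l0 <- log(total / ctx$alpha_fp)
  f <- function(lfe3) {
    fe3 <- exp(lfe3)
    d <- ctx$alpha_fp * fe3 + sid_bound(ctx, fe3)
    for (nm in c("dom", "pom")) {
      if (!is.null(ctx[[nm]])) {
        d <- d + phase_eval(ctx[[nm]], fe3, chis[nm], ctx)$fe_bound
      }
    }
    d / total - 1
  }
  exp(bracket_root(f, l0 - 80, l0 + 2))
}

assemble_result <- function(ctx, pr, fe3, chis, capped, converged, iterations,
                            method) {
  fe_prime <- ctx$alpha_fp * fe3
  fe_sid <- sid_bound(ctx, fe3)
  fe_dom <- if (!is.null(ctx$dom)) phase_eval(ctx$dom, fe3, chis["dom"], ctx)$fe_bound else 0
  fe_pom <- if (!is.null(ctx$pom)) phase_eval(ctx$pom, fe3, chis["pom"], ctx)$fe_bound else 0
  auth <- if (capped) pr$total_fe - (fe_prime + fe_sid + fe_dom + fe_pom) else 0
  if (capped && auth < -1e-12 * max(pr$total_fe, 1e-300)) {
    abort("internal consistency error: negative authFeOH in capped branch.")
  }
  auth <- max(auth, 0)
  si <- if (!is.null(ctx$fe3_cap)) {
    log10(max(fe3, 1e-300) / ctx$fe3_cap)
  } else {
    NA_real_
  }
  structure(
    list(fe3_free = fe3, fe_prime = fe_prime, fe_dom = fe_dom,
         fe_sid = fe_sid, fe_pom = fe_pom, auth_feoh = auth,
         chi_dom = unname(chis["dom"]), chi_pom = unname(chis["pom"]),
         saturation_index = si, capped = capped, converged = converged,
         iterations = iterations, method = method,
         total_fe = pr$total_fe, ph_free = ctx$ph_free, ctx = ctx,
         problem = pr),
    class = "fe_speciation"
  )
}

#' Solve a speciation problem
#'
#' Damped Newton iteration on the log-transformed unknowns (free Fe3+ and
#' the Donnan Boltzmann factors) closing the Fe mass balance and the charge
#' balance of each organic phase; if precipitation is allowed and the Fe3+
#' activity exceeds the ferrihydrite cap, the system is re-solved with Fe3+
#' fixed at the cap and the authigenic pool takes up the remainder.
#' Convergence requires a maximum scaled residual below `1e-10`; on Newton
#' failure the nested-bisection solver [bisect_equilibrium()] is used
#' automatically and the result is flagged (`method = "bisection"`).
#'
#' @param problem An `fe_problem` from [speciation_problem()].
#' @param warm Optional previous `fe_speciation` result used as the initial
#'   guess (speeds up transect sweeps).
#' @return An `fe_speciation` result: pools `fe_prime`, `fe_dom`, `fe_sid`,
#'   `fe_pom`, `auth_feoh` (mol L-1) summing to the total, Boltzmann factors,
#'   saturation index, and convergence diagnostics. Use [tidy()] for a tibble
#'   view and [occupied_affinity()] for effective affinities.
#' @examples
#' pr <- speciation_problem(5e-10, ph_total = 7.8, temp_c = 5, salinity = 34.7,
#'                          dom = dom_phase(1.6e-6), allow_mineral = TRUE)
#' res <- solve_equilibrium(pr)
#' tidy(res)
#' @export
solve_equilibrium <- function(problem, warm = NULL) {
  ctx <- build_context(problem)
  if (problem$total_fe == 0) {
    chis <- solve_chis_at_fe3(ctx, 0)
    return(assemble_result(ctx, problem, 0, chis, FALSE, TRUE, 0L, "newton"))
  }
  res <- tryCatch(
    newton_path(ctx, problem, warm),
    error = function(e) NULL
  )
  if (is.null(res) || !res$converged) {
    out <- bisect_equilibrium(problem)
    out$method <- "bisection_fallback"
    return(out)
  }
  res
}

newton_path <- function(ctx, problem, warm = NULL) {
  # initial guess: inorganic-only Fe3+, refined by a coarse pre-bracketing
  # with chi = 1, then full Newton
  if (!is.null(warm) && warm$fe3_free > 0) {
    fe30 <- warm$fe3_free
    chis0 <- c(dom = max(warm$chi_dom, 1e-6), pom = max(warm$chi_pom, 1e-6))
  } else {
    chis0 <- solve_chis_at_fe3(ctx, ctx$total_fe / ctx$alpha_fp)
    fe30 <- mass_balance_fe3(ctx, chis0)
  }
  u0 <- log(fe30)
  for (nm in c("dom", "pom")) if (!is.null(ctx[[nm]])) u0 <- c(u0, log(chis0[nm]))
  ns <- newton_solve(u0, function(u) eq_residual(u, ctx, fe3_fixed = NULL))
  if (!ns$converged) return(list(converged = FALSE))
  i <- 1
  fe3 <- exp(ns$u[i])
  chis <- c(dom = 1, pom = 1)
  for (nm in c("dom", "pom")) {
    if (!is.null(ctx[[nm]])) {
      i <- i + 1
      chis[nm] <- exp(ns$u[i])
    }
  }
  iters <- ns$iterations
  if (!is.null(ctx$fe3_cap) && fe3 > ctx$fe3_cap) {
    fe3 <- ctx$fe3_cap
    if (!is.null(ctx$dom) || !is.null(ctx$pom)) {
      u0 <- numeric(0)
      for (nm in c("dom", "pom")) if (!is.null(ctx[[nm]])) u0 <- c(u0, log(chis[nm]))
      ns2 <- newton_solve(u0, function(u) eq_residual(u, ctx, fe3_fixed = fe3))
      if (!ns2$converged) return(list(converged = FALSE))
      i <- 0
      for (nm in c("dom", "pom")) {
        if (!is.null(ctx[[nm]])) {
          i <- i + 1
          chis[nm] <- exp(ns2$u[i])
        }
      }
      iters <- iters + ns2$iterations
    }
    return(assemble_result(ctx, problem, fe3, chis, TRUE, TRUE, iters, "newton"))
  }
  assemble_result(ctx, problem, fe3, chis, FALSE, TRUE, iters, "newton")
}

#' Nested bracketing-bisection equilibrium solver (verification oracle)
#'
#' Independent solver for the same system as [solve_equilibrium()]: nested
#' bracketed root finding, with the outer level on the DOM Boltzmann factor,
#' the middle level on the POM Boltzmann factor and the inner level on free
#' Fe3+ (each residual is monotone in its own unknown at fixed others).
#' Brackets widen geometrically up to a bound before erroring. Slower but
#' structurally independent of the Newton path; used for cross-checks and as
#' an automatic fallback.
#'
#' @inheritParams solve_equilibrium
#' @return An `fe_speciation` result with `method = "bisection"`.
#' @export
bisect_equilibrium <- function(problem) {
  ctx <- build_context(problem)
  if (problem$total_fe == 0) {
    chis <- solve_chis_at_fe3(ctx, 0)
    return(assemble_result(ctx, problem, 0, chis, FALSE, TRUE, 0L, "bisection"))
  }
  solve_inner <- function(chis, fe3_fixed = NULL) {
    if (!is.null(fe3_fixed)) return(fe3_fixed)
    mass_balance_fe3(ctx, chis)
  }
  run_levels <- function(fe3_fixed = NULL) {
    chis <- c(dom = 1, pom = 1)
    if (!is.null(ctx$dom)) {
      res_d <- function(lchid) {
        chis["dom"] <<- exp(lchid)
        if (!is.null(ctx$pom)) {
          res_p <- function(lchip) {
            chis["pom"] <<- exp(lchip)
            fe3 <- solve_inner(chis, fe3_fixed)
            phase_eval(ctx$pom, fe3, chis["pom"], ctx)$charge
          }
          chis["pom"] <<- exp(bracket_root(res_p, -14, 14))
        }
        fe3 <- solve_inner(chis, fe3_fixed)
        phase_eval(ctx$dom, fe3, chis["dom"], ctx)$charge
      }
      chis["dom"] <- exp(bracket_root(res_d, -14, 14))
    } else if (!is.null(ctx$pom)) {
      res_p <- function(lchip) {
        chis["pom"] <<- exp(lchip)
        fe3 <- solve_inner(chis, fe3_fixed)
        phase_eval(ctx$pom, fe3, chis["pom"], ctx)$charge
      }
      chis["pom"] <- exp(bracket_root(res_p, -14, 14))
    }
    list(chis = chis, fe3 = solve_inner(chis, fe3_fixed))
  }
  lv <- run_levels()
  if (!is.null(ctx$fe3_cap) && lv$fe3 > ctx$fe3_cap) {
    lv <- run_levels(fe3_fixed = ctx$fe3_cap)
    return(assemble_result(ctx, problem, ctx$fe3_cap, lv$chis, TRUE, TRUE,
                           NA_integer_, "bisection"))
  }
  assemble_result(ctx, problem, lv$fe3, lv$chis, FALSE, TRUE, NA_integer_,
                  "bisection")
}

#' Saturation index of a solved state
#'
#' \eqn{SI = \log_{10}(\{Fe^{3+}\}\{H^+\}^{-3} / K_s(T))}: zero at the
#' solubility cap, negative when undersaturated. Equilibrium output never
#' reports SI > 0; supersaturation is only meaningful for hypothetical
#' uncapped states.
#'
#' @param result An `fe_speciation`.
#' @return Dimensionless saturation index (NA if no mineral configured).
#' @export
saturation_index <- function(result) {
  result$saturation_index
}

#' @export
print.fe_speciation <- function(x, ...) {
  cat("<fe_speciation> total Fe =", format(x$total_fe), "mol/L;",
      if (x$capped) "at solubility cap;" else "undersaturated;",
      "method:", x$method, "\n")
  pools <- c(fe_prime = x$fe_prime, fe_dom = x$fe_dom, fe_sid = x$fe_sid,
             fe_pom = x$fe_pom, auth_feoh = x$auth_feoh)
  print(round(pools / max(x$total_fe, 1e-300), 4))
  invisible(x)
}

#' @method tidy fe_speciation
#' @param x An `fe_speciation` result.
#' @param ... Unused.
#' @export
tidy.fe_speciation <- function(x, ...) {
  conc <- c(x$fe_prime, x$fe_dom, x$fe_sid, x$fe_pom, x$auth_feoh)
  tibble(
    pool = c("fe_prime", "fe_dom", "fe_sid", "fe_pom", "auth_feoh"),
    conc = conc,
    fraction = conc / max(x$total_fe, 1e-300)
  )
}

#' @method glance fe_speciation
#' @param x An `fe_speciation` result.
#' @param ... Unused.
#' @export
glance.fe_speciation <- function(x, ...) {
  tibble(
    total_fe = x$total_fe, fe3_free = x$fe3_free,
    saturation_index = x$saturation_index, capped = x$capped,
    chi_dom = x$chi_dom, chi_pom = x$chi_pom,
    converged = x$converged, method = x$method
  )
}
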