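#' One-compartment IV bolus parameter set
#'
#' Bundles the volume of distribution `Vd` (L), the first-order elimination
#' rate constant `ke` (1/h) and the administered bolus dose (mg).
#'
#' @param Vd Volume of distribution in litres, > 0.
#' @param ke Elimination rate constant in 1/h, > 0.
#' @param dose Administered amount in mg, >= 0.
#' @return An object of class `onecomp_params`.
#' @export
onecomp_params <- function(Vd, ke, dose) {
  stopifnot(is.numeric(Vd), is.numeric(ke), is.numeric(dose))
  if (any(!is.finite(Vd)) || any(Vd <= 0)) stop("Vd must be finite and > 0")
  if (any(!is.finite(ke)) || any(ke <= 0)) stop("ke must be finite and > 0")
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be finite and >= 0")
  structure(list(Vd = Vd, ke = ke, dose = dose), class = "onecomp_params")
}

#' Right-hand side of the one-compartment elimination ODE
#'
#' `dC/dt = -ke * C`: first-order elimination from a single well-stirred
#' compartment.
#'
#' @param C Concentration in mg/L.
#' @param t Time in hours (unused; the system is autonomous).
#' @param p An [onecomp_params()] object.
#' @return The concentration derivative in mg/L/h.
#' @export
onecomp_rhs <- function(C, t, p) {
  if (any(!is.finite(C))) stop("non-finite concentration passed to onecomp_rhs")
  -p$ke * C
}

#' Initial concentration after an IV bolus
#'
#' The dose distributes instantaneously: `C(0) = dose / Vd`.
#'
#' @param p An [onecomp_params()] object.
#' @return Initial concentration in mg/L.
#' @export
onecomp_initial <- function(p) {
  p$dose / p$Vd
}

#' Closed-form solution of the one-compartment IV bolus model
#'
#' `C(t) = (dose / Vd) * exp(-ke * t)`. Used as the exact oracle for numeric
#' ODE solves and for fast cohort simulation.
#'
#' @param t Times in hours, >= 0 (vectorised).
#' @param p An [onecomp_params()] object.
#' @return Concentrations in mg/L.
#' @export
onecomp_closed_form <- function(t, p) {
  if (any(t < 0)) stop("negative time passed to onecomp_closed_form")
  (p$dose / p$Vd) * exp(-p$ke * t)
}

#' Reference physiology for the minimal PBPK mAb model
#'
#' Reads the versioned CSV resource with reference volumes, lymph flows and
#' the lymphatic reflection coefficient at a 70 kg reference human. The
#' values follow the minimal-PBPK formulation for monoclonal antibodies
#' (plasma / lymph / tight-tissue ISF / leaky-tissue ISF compartments,
#' convection-driven distribution); they are adopted literature-style
#' reference values and can be overridden without code changes.
#'
#' @param path Optional path to an alternative CSV with the same layout.
#' @return A named list with `ref_weight`, `V_plasma`, `V_lymph`, `V_tight`,
#'   `V_leaky`, `L`, `L1`, `L2`, `sigma_L`.
#' @export
reference_physiology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mpbpk_reference_physiology.csv",
                        package = "dpinns", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- as.list(stats::setNames(tab$value, tab$parameter))
  needed <- c("ref_weight", "V_plasma", "V_lymph", "V_tight", "V_leaky",
              "L", "L1", "L2", "sigma_L")
  missing <- setdiff(needed, names(vals))
  if (length(missing)) stop("reference physiology CSV missing: ",
                            paste(missing, collapse = ", "))
  vals[needed]
}

#' Scale mPBPK physiology to a body weight
#'
#' All volumes and lymph flows scale linearly with body weight relative to
#' the reference; the lymphatic reflection coefficient is weight-invariant.
#' The flow partition `L1 + L2 = L` is preserved exactly.
#'
#' @param body_weight Body weight in kg, > 0.
#' @param ref Reference physiology, see [reference_physiology()].
#' @return An object of class `mpbpk_physiology`.
#' @export
scale_physiology <- function(body_weight, ref = reference_physiology()) {
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a single positive number")
  }
  s <- body_weight / ref$ref_weight
  structure(list(
    body_weight = body_weight,
    V_plasma = ref$V_plasma * s,
    V_lymph  = ref$V_lymph * s,
    V_tight  = ref$V_tight * s,
    V_leaky  = ref$V_leaky * s,
    L  = ref$L * s,
    L1 = ref$L1 * s,
    L2 = ref$L2 * s,
    sigma_L = ref$sigma_L
  ), class = "mpbpk_physiology")
}

#' mPBPK estimands: clearance and vascular reflection coefficients
#'
#' @param CLp Plasma clearance in L/h, > 0.
#' @param sigma1 Vascular reflection coefficient of tight tissues.
#' @param sigma2 Vascular reflection coefficient of leaky tissues. Must
#'   satisfy `0 < sigma2 < sigma1 < 1`: tight endothelium reflects more.
#' @return An object of class `mpbpk_estimands`.
#' @export
mpbpk_estimands <- function(CLp, sigma1, sigma2) {
  if (!is.finite(CLp) || CLp <= 0) stop("CLp must be > 0")
  if (!(sigma1 > 0 && sigma1 < 1)) stop("sigma1 must lie in (0, 1)")
  if (!(sigma2 > 0 && sigma2 < sigma1)) {
    stop("sigma2 must lie in (0, sigma1): tight tissues reflect more than leaky")
  }
  structure(list(CLp = CLp, sigma1 = sigma1, sigma2 = sigma2),
            class = "mpbpk_estimands")
}

#' Constant-rate IV infusion schedule
#'
#' @param dose Total administered amount (mg), >= 0.
#' @param T_inf Infusion duration in hours, > 0.
#' @return An object of class `infusion_schedule`.
#' @export
infusion_schedule <- function(dose, T_inf) {
  if (!is.finite(T_inf) || T_inf <= 0) stop("T_inf must be > 0")
  if (!is.finite(dose) || dose < 0) stop("dose must be >= 0")
  structure(list(dose = dose, T_inf = T_inf), class = "infusion_schedule")
}

#' Right-hand side of the minimal PBPK mAb model
#'
#' Four states in fixed order (plasma, tight-tissue ISF, leaky-tissue ISF,
#' lymph), all in mg/L. Distribution is convective: plasma-to-ISF transport
#' is filtered by the vascular reflection coefficients `sigma1`/`sigma2`,
#' lymphatic return by `sigma_L`, and the mAb is eliminated only from
#' plasma at clearance `CLp`. The zero-order infusion input `dose/T_inf`
#' is active for `t <= T_inf` and zero afterwards.
#'
#' @param state Numeric length-4 state vector `(plasma, tight, leaky, lymph)`.
#' @param t Time in hours.
#' @param phys An `mpbpk_physiology` from [scale_physiology()].
#' @param est An [mpbpk_estimands()] object.
#' @param inf An [infusion_schedule()] object.
#' @return Length-4 vector of concentration derivatives (mg/L/h).
#' @export
mpbpk_rhs <- function(state, t, phys, est, inf) {
  if (length(state) != 4 || any(!is.finite(state))) {
    stop("state must be a finite length-4 vector (plasma, tight, leaky, lymph)")
  }
  Cp <- state[1]; Ct <- state[2]; Cl <- state[3]; Cly <- state[4]
  input <- if (t <= inf$T_inf) inf$dose / inf$T_inf else 0
  dCp <- (input + Cly * phys$L -
            Cp * phys$L1 * (1 - est$sigma1) -
            Cp * phys$L2 * (1 - est$sigma2) -
            Cp * est$CLp) / phys$V_plasma
  dCt <- (phys$L1 * (1 - est$sigma1) * Cp -
            phys$L1 * (1 - phys$sigma_L) * Ct) / phys$V_tight
  dCl <- (phys$L2 * (1 - est$sigma2) * Cp -
            phys$L2 * (1 - phys$sigma_L) * Cl) / phys$V_leaky
  dCly <- (phys$L1 * (1 - phys$sigma_L) * Ct +
             phys$L2 * (1 - phys$sigma_L) * Cl -
             Cly * phys$L) / phys$V_lymph
  c(dCp, dCt, dCl, dCly)
}

# System matrix and input vector of the (linear) mPBPK ODE: dC/dt = M C + g,
# with g nonzero only during the infusion window.
mpbpk_system_matrix <- function(phys, est) {
  k1 <- phys$L1 * (1 - est$sigma1)
  k2 <- phys$L2 * (1 - est$sigma2)
  kL1 <- phys$L1 * (1 - phys$sigma_L)
  kL2 <- phys$L2 * (1 - phys$sigma_L)
  M <- matrix(0, 4, 4)
  M[1, 1] <- -(k1 + k2 + est$CLp) / phys$V_plasma
  M[1, 4] <- phys$L / phys$V_plasma
  M[2, 1] <- k1 / phys$V_tight
  M[2, 2] <- -kL1 / phys$V_tight
  M[3, 1] <- k2 / phys$V_leaky
  M[3, 3] <- -kL2 / phys$V_leaky
  M[4, 2] <- kL1 / phys$V_lymph
  M[4, 3] <- kL2 / phys$V_lymph
  M[4, 4] <- -phys$L / phys$V_lymph
  M
}

#' Solve the minimal PBPK model
#'
#' The system is linear with a piecewise-constant input, so the default
#' solver uses the eigendecomposition of the system matrix to evaluate the
#' matrix-exponential solution exactly (up to floating point), restarting
#' at the end of infusion. `method = "lsoda"` integrates numerically with
#' an exact solver restart at `T_inf` and serves as an independent check.
#'
#' @param times Output times in hours (nonnegative, increasing).
#' @param phys,est,inf Model components, see [mpbpk_rhs()].
#' @param method `"matexp"` (default) or `"lsoda"`.
#' @return Matrix with `length(times)` rows and columns
#'   `plasma`, `tight`, `leaky`, `lymph`.
#' @export
mpbpk_solve <- function(times, phys, est, inf, method = c("matexp", "lsoda")) {
  method <- match.arg(method)
  if (any(times < 0) || is.unsorted(times)) {
    stop("times must be nonnegative and increasing")
  }
  M <- mpbpk_system_matrix(phys, est)
  g <- c(inf$dose / inf$T_inf / phys$V_plasma, 0, 0, 0)
  out <- matrix(0, length(times), 4,
                dimnames = list(NULL, c("plasma", "tight", "leaky", "lymph")))
  if (method == "matexp") {
    eg <- eigen(M)
    P <- eg$vectors
    lam <- eg$values
    Pinv <- solve(P)
    # particular solution during infusion: C(t) = (expm(Mt) - I) M^-1 g
    Minv_g <- solve(M, g)
    expMt <- function(t) Re(P %*% (exp(lam * t) * Pinv))
    C_inf_end <- as.numeric((expMt(inf$T_inf) - diag(4)) %*% Minv_g)
    for (i in seq_along(times)) {
      t <- times[i]
      out[i, ] <- if (t <= inf$T_inf) {
        as.numeric((expMt(t) - diag(4)) %*% Minv_g)
      } else {
        as.numeric(expMt(t - inf$T_inf) %*% C_inf_end)
      }
    }
  } else {
    rhs <- function(t, y, parms) list(as.numeric(M %*% y) +
                                        if (t <= inf$T_inf) g else c(0, 0, 0, 0))
    grid <- sort(unique(c(0, inf$T_inf, times)))
    sol <- deSolve::lsoda(c(0, 0, 0, 0), grid, rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    idx <- match(times, grid)
    out[] <- as.matrix(sol[idx, 2:5, drop = FALSE])
  }
  out
}

#' Map unconstrained reals to ordered reflection coefficients
#'
#' `sigma1 = invlogit(sigma1_raw)` and
#' `sigma2 = sigma1 * invlogit(sigma2_raw)`, guaranteeing
#' `0 < sigma2 < sigma1 < 1` for any inputs. Vectorised and monotone in
#' each raw argument.
#'
#' @param sigma1_raw,sigma2_raw Unconstrained reals.
#' @return List with elements `sigma1`, `sigma2`.
#' @export
constrain_reflection <- function(sigma1_raw, sigma2_raw) {
  invlogit <- function(x) 1 / (1 + exp(-x))
  s1 <- invlogit(sigma1_raw)
  list(sigma1 = s1, sigma2 = s1 * invlogit(sigma2_raw))
}

#' Retrieve a registered pharmacokinetic model
#'
#' The registry keys the two shipped systems: `"onecomp_iv_bolus"`
#' (one-state first-order elimination after an IV bolus, parameters
#' `Vd`, `ke`) and `"mpbpk_mab"` (four-state minimal PBPK for monoclonal
#' antibodies, stochastic parameter `CLp`, point parameters `sigma1`,
#' `sigma2`). The returned specification carries the state dimension,
#' parameter names, an `rhs(state, t, params)` closure and an
#' `initial_condition(params)` closure.
#'
#' @param name Registered model name.
#' @param ... Model-specific fixed quantities: `dose` for
#'   `"onecomp_iv_bolus"`; `phys` (an `mpbpk_physiology`) and `inf` (an
#'   [infusion_schedule()]) for `"mpbpk_mab"`.
#' @return An object of class `ode_model_spec`.
#' @export
pk_model <- function(name, ...) {
  args <- list(...)
  if (name == "onecomp_iv_bolus") {
    dose <- args$dose
    if (is.null(dose)) stop("onecomp_iv_bolus requires a dose")
    spec <- list(
      name = name, n_states = 1L, observed_states = 1L,
      parameter_names = c("Vd", "ke"),
      rhs = function(state, t, params) {
        onecomp_rhs(state, t, onecomp_params(params[["Vd"]], params[["ke"]], dose))
      },
      initial_condition = function(params) dose / params[["Vd"]],
      dose = dose
    )
  } else if (name == "mpbpk_mab") {
    phys <- args$phys; inf <- args$inf
    if (is.null(phys) || is.null(inf)) stop("mpbpk_mab requires phys and inf")
    spec <- list(
      name = name, n_states = 4L, observed_states = 1L,
      state_names = c("plasma", "tight", "leaky", "lymph"),
      parameter_names = c("CLp", "sigma1", "sigma2"),
      rhs = function(state, t, params) {
        est <- mpbpk_estimands(params[["CLp"]], params[["sigma1"]], params[["sigma2"]])
        mpbpk_rhs(state, t, phys, est, inf)
      },
      initial_condition = function(params) c(0, 0, 0, 0),
      phys = phys, inf = inf
    )
  } else {
    stop("unknown model '", name, "'; registered models: ",
         "onecomp_iv_bolus, mpbpk_mab")
  }
  structure(spec, class = "ode_model_spec")
}
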