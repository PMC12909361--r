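# Shared fixtures built in code at test time.

table1_truth <- c(mu_ke = 0.116, sd_ke = 0.046, mu_Vd = 15.000,
                  sd_Vd = 1.500, sigma = 0.100)

default_onecomp_params <- function() onecomp_params(Vd = 15, ke = log(2) / 6,
                                                    dose = 300)

default_mpbpk <- function(weight = 70) {
  ref <- reference_physiology()
  list(phys = scale_physiology(weight, ref),
       est = mpbpk_estimands(CLp = 0.0115, sigma1 = 0.8378, sigma2 = 0.7529),
       inf = infusion_schedule(dose = weight, T_inf = 1.5),
       ref = ref)
}

# tiny D-PINN setup shared by loss/gradient tests
tiny_setup <- function(model_kind = c("onecomp", "mpbpk"), seed = 42,
                       denoise = "joint", n_cp = 7L, n_s = 5L) {
  model_kind <- match.arg(model_kind)
  set.seed(seed)
  if (model_kind == "onecomp") {
    data <- simulate_onecomp_study()$data
    model <- pk_model("onecomp_iv_bolus", dose = 300)
    cfg <- dpinn_config(n_collocation = n_cp, n_samples = n_s,
                        iterations = 0L, n_ic_samples = n_s,
                        denoise = denoise)
  } else {
    data <- simulate_mab_cohort(n_subjects = 15)$data
    model <- dpinn_mpbpk_model()
    cfg <- dpinn_config(n_collocation = n_cp, n_samples = n_s,
                        iterations = 0L, sigma_fixed = 0.1,
                        denoise = denoise)
  }
  setup <- dpinns:::dpinn_setup(data, model, cfg)
  par0 <- dpinns:::dpinn_init_par(data, model, cfg, setup)
  list(data = data, model = model, cfg = cfg, setup = setup, par0 = par0)
}

core_loss <- function(ts, par, draws, want_grad = FALSE) {
  dpinns:::.dpinn_loss_grad(par, ts$setup$cfg, draws$z, draws$u, draws$bw,
                            draws$zeta, draws$om, want_grad)
}
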