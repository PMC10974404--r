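# Shared fixtures, built in code at test time.

# A short noiseless subject record (30 s keeps unit tests fast; the
# acceptance suite uses full 2-min records).
make_record <- function(hb = 14, spo2 = 0.97, hr = 72, seed = 3,
                        duration = 30, noise = noise_off(), age = 40,
                        gender = 1) {
  st <- physio_state(hb_total = hb, spo2 = spo2, heart_rate = hr)
  list(id = "T0001",
       ppg = generate_ppg(st, noise = noise, duration = duration, seed = seed),
       age = age, gender = gender, hb_ref = hb, state = st)
}

# Synthetic regression problem with a smooth nonlinear response, used for
# ELM/ensemble behaviour tests (no PPG involved).
make_regression <- function(n = 150, d = 10, noise_sd = 0.1, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- sin(X[, 1]) + 0.5 * X[, 2]^2 + X[, 3] + rnorm(n, sd = noise_sd)
  list(X = X, y = y)
}
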