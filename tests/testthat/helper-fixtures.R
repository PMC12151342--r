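# Shared simulated fixtures, built once per test run and cached. Everything
# is generated in code; seeds are fixed so the suite is reproducible.
.fx <- new.env(parent = emptyenv())

fixture_cached <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fixture_experiments <- function(n = 4, duration_s = 180) {
  fixture_cached(sprintf("exps_%d_%d", n, duration_s), function() {
    pol <- generative_policy()
    f <- plaid_field()
    lapply(seq_len(n), function(i) {
      simulate_fish(pol,
        field = f, duration_s = duration_s,
        seed = 500 + i, id = paste0("fx", i)
      )
    })
  })
}

fixture_inputs <- function() {
  fixture_cached("inputs", function() {
    exps <- fixture_experiments()
    build_inputs(exps, bouts = lapply(exps, true_bouts))
  })
}

fixture_encoder <- function() {
  fixture_cached("encoder", function() {
    train_encoder(fixture_inputs(), epochs = 30, batch = 256, lr = 2e-3, seed = 3)
  })
}
# ---- study-scale fixtures shared by the acceptance suite ----------------
# 20 closed-loop experiments of 10 minutes each; encoder fits use 40 epochs
# with minibatches of 1024 at step 2e-3 (linear lr-batch scaling of the
# 256 / 1e-3 default). Built lazily and cached for the whole run.

acc_experiments <- function() {
  fixture_cached("acc_exps", function() {
    pol <- generative_policy()
    f <- plaid_field()
    lapply(1:20, function(i) {
      simulate_fish(pol,
        field = f, duration_s = 600, seed = 100 + i,
        id = sprintf("acc%02d", i)
      )
    })
  })
}

acc_inputs <- function() {
  fixture_cached("acc_inputs", function() build_inputs(acc_experiments()))
}

acc_fit_settings <- list(epochs = 40, batch = 1024, lr = 2e-3)

acc_fits <- function(n_fits = 10) {
  fixture_cached("acc_fits", function() {
    inp <- acc_inputs()
    lapply(seq_len(n_fits), function(s) {
      m <- train_encoder(inp,
        epochs = acc_fit_settings$epochs,
        batch = acc_fit_settings$batch,
        lr = acc_fit_settings$lr, seed = s
      )
      list(model = m, rf = extract_rf(m, inp, n_eval_samples = 20000, seed = s))
    })
  })
}

acc_perm_fits <- function(n_fits = 10) {
  fixture_cached("acc_perm_fits", function() {
    perm <- circular_permutation_control(acc_inputs(), 1 / 3)
    lapply(seq_len(n_fits), function(s) {
      m <- train_encoder(perm,
        epochs = acc_fit_settings$epochs,
        batch = acc_fit_settings$batch,
        lr = acc_fit_settings$lr, seed = 50 + s
      )
      list(
        model = m, perm = perm,
        rf = extract_rf(m, perm, n_eval_samples = 20000, seed = 50 + s)
      )
    })
  })
}

acc_pairs <- function() {
  fixture_cached("acc_pairs", function() {
    simulate_experiment_pairs(20, duration_s = 180, seed = 700)
  })
}
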