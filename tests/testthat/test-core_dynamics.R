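test_that("leak current vanishes at rest and is antisymmetric about it", {
  p <- neuron_params(Rm = 1.0e8)
  expect_equal(leak_current(p$Vr, p), 0)
  expect_equal(leak_current(p$Vr + 0.010, p), -1.0e-10)
  expect_equal(leak_current(p$Vr - 0.010, p), +1.0e-10)
})

test_that("adaptation current is zero at rest or without conductance and scales linearly", {
  p <- neuron_params(adaptive = TRUE)
  expect_equal(adaptation_current(0, p$Vr + 0.02, p), 0)
  expect_equal(adaptation_current(1e-8, p$Vr, p), 0)
  expect_equal(adaptation_current(1e-8, p$Vr + 0.02, p), 2e-10)
})

test_that("single Euler decay steps match hand evaluation and reject unstable steps", {
  p <- neuron_params(adaptive = TRUE, tau_adapt = 1e-2)
  expect_equal(decay_adaptation(0, 1e-4, p), 0)
  expect_equal(decay_adaptation(1e-8, 1e-4, p), 0.99e-8)
  expect_error(decay_adaptation(1e-8, 1e-2, p), "invalid step")

  syn <- synapse_params(tau_syn = 1e-3)
  expect_equal(decay_synaptic_current(0, 1e-4, syn), 0)
  expect_equal(decay_synaptic_current(1e-9, 1e-4, syn), 0.9e-9)
  expect_error(decay_synaptic_current(1e-9, 2e-3, syn), "invalid step")
})

test_that("repeated Euler decay converges to the closed-form exponential", {
  # stepping over one time constant should approach g0 * exp(-1), with the
  # error shrinking linearly in dt (first-order scheme)
  p <- neuron_params(adaptive = TRUE, tau_adapt = 0.25)
  g0 <- 1e-8
  err <- vapply(c(1000, 2000), function(n) {
    dt <- p$tau_adapt / n
    g <- g0
    for (i in seq_len(n)) g <- decay_adaptation(g, dt, p)
    abs(g - g0 * exp(-1))
  }, numeric(1))
  expect_lt(err[1] / (g0 * exp(-1)), 1e-3)
  expect_lt(err[2], err[1] / 1.9)

  syn <- synapse_params(peak_current = 1e-9, tau_syn = 0.01)
  s <- syn$peak_current
  n <- 1000
  for (i in seq_len(n)) s <- decay_synaptic_current(s, syn$tau_syn / n, syn)
  expect_equal(s, syn$peak_current * exp(-1), tolerance = 1e-3)
})

test_that("the resting state is a fixed point of the neuron update for any dt", {
  p <- neuron_params()
  for (dt in c(1e-5, 1e-4, 1e-3)) {
    out <- step_neuron(neuron_state(p), p, 0, 0, dt)
    expect_identical(out$state$V, p$Vr)
    expect_false(out$fired)
    expect_identical(out$state$refractory_remaining, 0)
  }
})

test_that("threshold crossing resets the membrane and arms the refractory hold", {
  p <- neuron_params(adaptive = TRUE)
  st <- neuron_state(p, V = p$Vthres - 1e-4)
  out <- step_neuron(st, p, 0, 1e-7, 1e-4)  # large kick
  expect_true(out$fired)
  expect_identical(out$state$V, p$Vreset)
  expect_identical(out$state$refractory_remaining, p$tau_r)
  expect_equal(out$state$g_adapt, p$delta_g_adapt)
  # recorded voltage is the pre-reset (clamped) excursion
  expect_gte(out$v_recorded, p$Vthres)

  # during the hold: pinned at Vreset, no firing, countdown shrinks,
  # adaptation keeps decaying
  held <- step_neuron(out$state, p, 0, 1e-7, 1e-4)
  expect_false(held$fired)
  expect_identical(held$state$V, p$Vreset)
  expect_identical(held$v_recorded, p$Vreset)
  expect_equal(held$state$refractory_remaining, p$tau_r - 1e-4)
  expect_lt(held$state$g_adapt, out$state$g_adapt)
})

test_that("subthreshold charging follows the closed-form RC solution to first order", {
  p <- neuron_params()
  tau_m <- p$Rm * p$Cm
  I <- 1e-10  # V_inf = Vr + 10 mV, below threshold
  v_inf <- p$Vr + p$Rm * I
  max_dev <- function(dt) {
    n <- ceiling(5 * tau_m / dt)
    st <- neuron_state(p)
    dev <- 0
    for (k in seq_len(n)) {
      st <- step_neuron(st, p, 0, I, dt)$state
      v_exact <- v_inf + (p$Vr - v_inf) * exp(-k * dt / tau_m)
      dev <- max(dev, abs(st$V - v_exact))
    }
    list(dev = dev, v_end = st$V)
  }
  coarse <- max_dev(tau_m / 1000)
  expect_equal(coarse$v_end, v_inf, tolerance = 0.01)
  fine <- max_dev(tau_m / 2000)
  expect_lt(fine$dev, coarse$dev / 1.9)  # halving dt at least halves the error
})

test_that("voltage clamping respects bounds, interior points and the disable switch", {
  expect_equal(clamp_voltage(-0.070), -0.070)
  expect_equal(clamp_voltage(+0.100), +0.060)
  expect_equal(clamp_voltage(-0.200), -0.090)
  expect_equal(clamp_voltage(-0.200, clamp_policy(enabled = FALSE)), -0.200)
  expect_equal(clamp_voltage(0.1, clamp_policy(v_min = -1, v_max = 1)), 0.1)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params(Vreset = -0.04, Vthres = -0.05))
  expect_error(neuron_params(Cm = 0))
  expect_error(neuron_params(adaptive = TRUE, tau_adapt = 0))
  expect_error(synapse_params(tau_syn = 0))
  expect_error(synapse_params(peak_current = -1e-9))
  expect_error(clamp_policy(v_min = 1, v_max = -1))
})
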