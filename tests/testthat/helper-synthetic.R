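# Shared small fixtures, built in code at load time.

default_cp <- make_input_function()

# cached default reference TAC on the 55-frame schedule (expensive enough
# to share across tests; read-only)
default_ref <- simulate_reference_tac(default_cp)

default_truth <- list(R1 = 1.2, k2 = 0.3, bpnd = 2.0)

# a short schedule for cheap image-level tests: 10 x 60 s
short_schedule <- frame_schedule(rep(60, 10))

# constant-concentration reference with an attached constant fine curve,
# for step-input closed forms
constant_reference <- function(value, total_min, n_frames = 40) {
  sched <- frame_schedule(rep(total_min * 60 / n_frames, n_frames))
  tac <- new_tac(
    (sched$start_s + sched$dur_s / 2) / 60, sched$dur_s / 60,
    rep(value, n_frames), schedule = sched)
  attr(tac, "fine") <- list(t = seq(0, total_min, by = 0.01),
                            y = rep(value, length(seq(0, total_min, by = 0.01))))
  tac
}
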