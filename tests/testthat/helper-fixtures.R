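# Shared fixtures, built once per test run. Everything is generated in code;
# no data files are read.

.fix <- new.env()

fixture_blood <- function() {
  if (is.null(.fix$blood)) .fix$blood <- gen_blood_dataset(seed = 42)
  .fix$blood
}

fixture_input <- function() {
  if (is.null(.fix$input)) {
    b <- fixture_blood()
    .fix$input <- suppressMessages(
      apply_parent_correction(build_plasma_curve(b, fit_plasma_ratio(b)),
                              fit_parent_fraction(b)))
  }
  .fix$input
}

fixture_schedule <- function() meppep_frame_schedule()

fixture_basis <- function() {
  if (is.null(.fix$basis))
    .fix$basis <- build_basis(fixture_input(), fixture_schedule())
  .fix$basis
}
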