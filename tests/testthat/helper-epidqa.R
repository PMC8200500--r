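## Shared fixtures: renders are generated in code at test time.

## default study config: 512x512, 0.5 mm isocenter sampling
studyConfig <- function(...) RenderConfig(...)

## smaller/faster grid for tests that do not need the 0.5 mm sampling
fastConfig <- function(...)
  RenderConfig(gridShape = c(256L, 256L), pixelSpacing = 1, ...)

## tiny grid for Winston-Lutz style small fields
wlConfig <- function(...)
  RenderConfig(gridShape = c(128L, 128L), pixelSpacing = 1.5, ...)

noiseless <- function(...) ErrorModel(noiseSigma = 0, ...)

expect_all_near <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max |diff| = %g (tol %g)", max(abs(x - y)), tol))
}
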