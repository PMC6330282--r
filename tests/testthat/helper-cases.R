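# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# small desk-scale phantom; memoised by key
fixture_phantom <- function(key = "default", noise = 0.05, seed = 11,
                            age = "4-8y", ...) {
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  spec <- phantom_spec(age_class = age, grid_shape = 32, voxel_mm = 2.5,
                       noise_sigma = noise, seed = seed, ...)
  .fixtures[[key]] <- build_phantom(spec, sprintf("S%s", key))
  .fixtures[[key]]
}

# a battery of cases across age classes
fixture_battery <- function(n = 4, noise = 0, seed0 = 50) {
  key <- sprintf("battery_%d_%g_%d", n, noise, seed0)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  ages <- c("2-4y", "4-8y", "8-11y", "11-14y")
  .fixtures[[key]] <- lapply(seq_len(n), function(i)
    build_phantom(phantom_spec(age_class = ages[(i - 1) %% 4 + 1],
                               grid_shape = 32, voxel_mm = 2.5,
                               noise_sigma = noise, seed = seed0 + i),
                  sprintf("S%02d", i)))
  .fixtures[[key]]
}

# minimal hand-built case (not via the generator) for window bookkeeping
toy_case <- function(nslices, n = 20, seed = 1) {
  set.seed(seed)
  sp <- 2
  mk <- function() as_volume(array(runif(nslices * n * n, 1, 100),
                                   c(nslices, n, n)), sp)
  structure(list(ute1 = mk(), ute2 = mk(), ct_hu = mk(),
                 te1_ms = 0.07, te2_ms = 2.46,
                 subject_id = "T01", exam_index = 1L),
            class = "phantom_case")
}

jac_of <- function(a, b) sum(a & b) / sum(a | b)
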