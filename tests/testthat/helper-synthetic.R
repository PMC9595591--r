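# Shared fixtures, built in code and memoized so expensive synthetic fields
# are generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_field <- function(seed = 1L, ...) {
  key <- paste0("field_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, generate_field(field_spec(seed = seed, ...)))
}

# full census + trace chain on a default field
analyzed_field <- function(seed = 1L, ...) {
  key <- paste0("analyzed_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, {
    fg <- default_field(seed = seed, ...)
    mask <- segment_somata(fg$field)
    neurites <- segment_neurites(fg$field, mask)
    skeleton <- skeletonize(neurites, fg$field$pixel_size_um)
    list(field = fg$field, truth = fg$truth, mask = mask,
         neurites = neurites, skeleton = skeleton)
  })
}

# exact Mann-Whitney p by full enumeration of group assignments (oracle)
mw_exact_p_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- length(x) * length(y) / 2
  # two-sided: as extreme or more extreme in either direction
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
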