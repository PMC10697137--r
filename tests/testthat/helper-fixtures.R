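# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture_parent <- function() {
  if (is.null(.fixture_cache$parent))
    .fixture_cache$parent <- build_repeat_protein(repeat_spec(n_repeats = 4))
  .fixture_cache$parent
}

# the canonical "design": clash-free state Y, passing gate
fixture_states <- function() {
  if (is.null(.fixture_cache$states))
    .fixture_cache$states <- assemble_states(fixture_parent(), hinge_spec(4, -1))
  .fixture_cache$states
}

# large-motion variant used for label-site distance changes
fixture_states_bigmove <- function() {
  if (is.null(.fixture_cache$bigmove))
    .fixture_cache$bigmove <- assemble_states(fixture_parent(), hinge_spec(4, 6))
  .fixture_cache$bigmove
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

random_rigid <- function(scale = 10) {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = scale))
}
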