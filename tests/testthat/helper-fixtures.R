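# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# One HRP post-2h image at default SNR with its segmentation, reused by
# several imaging tests.
hrp_image_fixture <- function() {
  fixture("hrp_img", function() {
    reg <- recap_regime("HRP", nucleus_count = 40)
    out <- gen_recap_image(reg, "post2h", shape = c(320L, 320L), seed = 7)
    out$nuclei <- segment_nuclei(out$image[, , 1])
    out
  })
}

# A tiny two-nucleus DAPI field with touching nuclei and distinct cores.
touching_nuclei_fixture <- function() {
  img <- matrix(0, 80, 80)
  for (ctr in list(c(40, 30), c(40, 52))) {
    d <- sqrt(outer((1:80 - ctr[1])^2, (1:80 - ctr[2])^2, "+"))
    img[d <= 12] <- pmax(img[d <= 12], 0.6 * exp(-d[d <= 12]^2 / (2 * 10^2)))
  }
  img / max(img)
}
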