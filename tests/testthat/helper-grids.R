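# random (taper, height, base) triples for resistance equivalence checks
random_triples <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    taper = runif(n, 0, 25),
    height = runif(n, 1, 8),
    base = runif(n, 5, 12)
  )
}

# closed-form block area, used as an independent check at zero taper
block_area <- function(w, l, h) 2 * w * h + 2 * l * h + w * l
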