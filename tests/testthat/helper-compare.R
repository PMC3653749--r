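# structural equality of two networks up to row order
expect_same_network <- function(a, b) {
  key <- function(d) do.call(paste, c(d, sep = "\r"))
  expect_setequal(key(a$species), key(b$species))
  expect_setequal(key(a$reactions), key(b$reactions))
  expect_setequal(key(a$edges), key(b$edges))
}
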