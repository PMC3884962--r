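# Shared small fixtures; everything is generated in code at test time.

tmp_tiff <- function() tempfile(fileext = ".tif")

# A quick solver-ready phantom at reduced size.
small_phantom <- function(geometry = "box", gamma = 1, sigma = 0, seed = 1,
                          shape = c(12, 24, 24)) {
  generate_phantom(phantom_spec(shape = shape, geometry = geometry,
                                c1 = 10, c2 = 2, gamma = gamma,
                                sigma = sigma, seed = seed))
}
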