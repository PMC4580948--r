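## shared small fixtures; everything is generated in code
geom1 <- oocyte_geometry("geometry1")
geom2 <- oocyte_geometry("geometry2")

## a reduced wild-type realization shared across fields/polymer tests
small_realization <- local({
  seeds <- sample_seeds(geom1, seeding_params("wildtype", N_A = 2000),
                        seed = 7)
  grow_cytoskeleton(seeds, polymer_params(), seed = 8)
})

## synthetic segment matrix builder (midpoints + unit orientations)
make_segments <- function(mid, ori) {
  ori <- ori / sqrt(rowSums(ori^2))
  m <- cbind(mid, ori)
  colnames(m) <- c("mx", "my", "mz", "ox", "oy", "oz")
  m
}
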