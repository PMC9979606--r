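# Independent explicit-loop oracle for every symmetry-function kind;
# deliberately written with scalar loops, sharing no code with the package's
# batched featurizer.
loop_descriptor <- function(geom, i, p) {
  d <- pairwise_distances(geom)
  fc <- function(r) if (r > p$rc) 0 else 0.5 * (cos(pi * r / p$rc) + 1)
  if (p$kind == "G2") {
    rs <- if (identical(p$rs, "min_rij"))
      min(d[upper.tri(d)]) else p$rs
    s <- 0
    for (j in setdiff(1:4, i))
      s <- s + exp(-p$eta * (d[i, j] - rs)^2) * fc(d[i, j])
    return(s)
  }
  s <- 0
  nb <- setdiff(1:4, i)
  for (a in 1:2) for (b in (a + 1):3) {
    j <- nb[a]; k <- nb[b]
    u <- geom$xyz[j, ] - geom$xyz[i, ]; v <- geom$xyz[k, ] - geom$xyz[i, ]
    cosang <- sum(u * v) / (d[i, j] * d[i, k])
    ang <- max(0, 1 + p$gamma * cosang)^p$zeta
    s <- s + if (p$kind == "G3")
      ang * exp(-p$eta * (d[i, j]^2 + d[i, k]^2 + d[j, k]^2)) *
        fc(d[i, j]) * fc(d[i, k]) * fc(d[j, k])
    else
      ang * exp(-p$eta * (d[i, j]^2 + d[i, k]^2)) *
        fc(d[i, j]) * fc(d[i, k])
  }
  2^(1 - p$zeta) * s
}
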