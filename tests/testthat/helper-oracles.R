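# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# U statistics by double loop: #(x>y) + 0.5 * #(x==y)
bruteU <- function(x, y) {
  u1 <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) u1 <- u1 + 1 else if (xi == yi) u1 <- u1 + 0.5
  }
  list(u1 = u1, u2 = length(x) * length(y) - u1)
}

# signed Cliff's delta by double loop
bruteDelta <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) gt <- gt + 1 else if (xi < yi) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# exhaustive single-linkage clustering via union-find on all pairs <= sep
bruteClusters <- function(x, y, sep = 2) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= sep) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# code of one cluster from its members' coordinates
bruteCode <- function(x, y) {
  n <- length(x)
  if (n == 1) return(1L)
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  g <- max(apply(d, 1, min))
  if (g <= 0.5) 2L else if (g <= 1) 3L else 4L
}

# random small abundance vector
randAbundance <- function(maxS = 8, maxN = 20) {
  S <- sample(1:maxS, 1)
  setNames(sample(1:maxN, S, replace = TRUE), paste0("s", seq_len(S)))
}

# tiny 2-unit toy observation set used in several files
toyObservations <- function() {
  data.frame(
    unit = c("f/ungrazed/Q1/S1", "f/ungrazed/Q1/S2", "f/ungrazed/Q1/S1"),
    species = c("A", "A", "B"),
    individual_number = c(2L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

toyTraits <- function(species) {
  data.frame(
    species = species,
    order = "Agaricales",
    trophic = "wood saprotroph",
    attachment = "wood-inhabiting",
    sporocarp = "agaricoid",
    geographic = "cosmopolitan",
    edibility = "unknown",
    stringsAsFactors = FALSE
  )
}
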