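# Build a population state carrying given mutations at given counts, for
# oracle-style tests of the transmission engine. Each mutation's copies are
# placed on randomly chosen gametes (one copy each, no within-mutation
# doubling), so different mutations start in linkage equilibrium.
state_with_mutations <- function(n, counts, effects = rep(0, length(counts)),
                                 loci = seq_along(counts),
                                 generation = 0L) {
  stopifnot(all(counts <= 2 * n))
  gametes <- rep(list(integer(0)), 2 * n)
  for (i in seq_along(counts)) {
    if (counts[i] > 0)
      for (g in sample.int(2 * n, counts[i]))
        gametes[[g]] <- sort(c(gametes[[g]], i))
  }
  mut <- data.frame(locus = as.integer(loci),
                    pos = 1000 * seq_along(counts),
                    effect = effects,
                    origin = rep(-1L, length(counts)),
                    count = as.integer(counts))
  G <- vapply(seq_len(n), function(i)
    sum(effects[c(gametes[[2 * i - 1]], gametes[[2 * i]])]), numeric(1))
  structure(
    list(generation = as.integer(generation), gametes = gametes,
         mutations = mut, baseline = 0, G = G, P = G),
    class = "population_state"
  )
}

# sorting helper: gamete ids must be ordered by (locus, pos); with loci
# distinct and pos increasing in id, plain sort is enough
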