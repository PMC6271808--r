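# small shared fixtures, built in code

toy_band_matrix <- function() {
  band_matrix(rbind(A = c(1, 1, 0, 0),
                    B = c(1, 0, 1, 0),
                    C = c(0, 1, 1, 1)),
              primers = c("P1", "P1", "P2", "P2"))
}

random_band_matrix <- function(n = 10, nb = 20, seed = 1) {
  set.seed(seed)
  v <- matrix(rbinom(n * nb, 1, runif(nb)[rep(seq_len(nb), each = n)]), n, nb)
  band_matrix(v, primers = rep(c("P1", "P2"), length.out = nb))
}

extdata <- function(f) system.file("extdata", f, package = "scotdiv")

primer_stats_fixture <- function() {
  read.delim(extdata("whipgrass_primer_stats.tsv"))
}

group_diversity_fixture <- function() {
  read.delim(extdata("whipgrass_group_diversity.tsv"))
}

# all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}
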