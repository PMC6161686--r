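# Shared fixtures, built once per test run.

# The default scenario (the study conditions) with its locus calls; most
# recovery tests read from this.
default_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_dataset(sim_scenario(seed = 1))
    sim
  }
})

default_calls <- local({
  calls <- NULL
  function() {
    if (is.null(calls)) {
      sim <- default_sim()
      calls <<- call_all_loci(sim$genome, sim$truth$loci, sim$reads)
    }
    calls
  }
})

pool_reads <- function(a, b) {
  x <- rbind(a, b)
  attr(x, "library_size") <- nrow(x)
  x
}

# A synthetic stem-loop structure with full pairing: `arm` stem pairs around
# a loop, via the external-structure reader (no folding involved).
make_test_structure <- function(arm = 30L, loop = 10L, energy = -40,
                                seq = NULL) {
  db <- paste0(strrep("(", arm), strrep(".", loop), strrep(")", arm))
  if (is.null(seq))
    seq <- paste0(strrep("G", arm), strrep("A", loop), strrep("C", arm))
  f <- tempfile()
  writeLines(c(seq, db, sprintf("energy=%g", energy)), f)
  on.exit(unlink(f))
  read_structure(f, "test")
}

# A read_stack built directly from a (start, length, count) table.
make_test_stack <- function(tab, window = c(0L, 100L), strand = "+",
                            library_size = 1e6) {
  structure(list(locus_id = "test", window = window, strand = strand,
                 table = tab[order(tab$start, tab$length), , drop = FALSE],
                 total = sum(tab$count), library_size = library_size),
            class = "read_stack")
}

# Failing criteria (among i-v) of a locus call, as a character vector.
failing_criteria <- function(cl) {
  cr <- cl$criteria
  f <- c(read_support = !cr$i_read_support$pass,
         overhang = !cr$ii_overhang$pass,
         homogeneity = !cr$iii_homogeneity$pass,
         energy = !cr$iv_energy$pass,
         pairing = !cr$v_pairing$pass)
  names(f)[f]
}

# Independent brute-force folding oracle: enumerate all legal nested
# structures (min loop 3) by recursion and return the minimum energy.
brute_force_fold <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pe <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) -2
    else if (p %in% c("AT", "TA", "GT", "TG")) -1
    else 0
  }
  f <- function(i, j) {
    if (i >= j - 3L) return(0)
    best <- f(i + 1L, j)
    for (k in (i + 4L):j) {
      e <- pe(b[i], b[k])
      if (e < 0) best <- min(best, e + f(i + 1L, k - 1L) + f(k + 1L, j))
    }
    best
  }
  f(1L, length(b))
}
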