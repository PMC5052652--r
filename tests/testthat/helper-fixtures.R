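# Shared fixtures, built in code. Everything is seeded so tests are
# deterministic; moderately expensive objects are built once per test run.

fix_env <- new.env()

# a mid-sized fossil birth-death tree reused by several files
shared_tree <- function(n = 60, seed = 101) {
  key <- paste0("tr", n, "_", seed)
  if (is.null(fix_env[[key]]))
    fix_env[[key]] <- sim_bd_tree(n, 0.065, 0.035, seed = seed)
  fix_env[[key]]
}

# hand-built 3-tip painted tree: ((A:1,B:1):1,C:2); root edge to (A,B)
# painted "0", A stays "0", B switches to "1" halfway, C mixed
toy_simmap <- function() {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  map <- tr
  # edge order in ape: (4->5), (5->A), (5->B), (4->C)
  map$maps <- list(c("0" = 1), c("0" = 1), c("0" = 0.5, "1" = 0.5),
                   c("0" = 1.2, "1" = 0.8))
  class(map) <- c("simmap", "phylo")
  map
}

# tip-date table placing every tip at its current age +/- 0 interval
exact_dates <- function(tree) {
  ages <- tip_ages(tree)
  data.frame(taxon = names(ages), FAD = ages, LAD = ages)
}
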