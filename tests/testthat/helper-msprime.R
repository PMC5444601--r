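# Independent coalescent oracle: msprime genealogies with a single
# branch-length-proportional mutation per locus, under the same clean
# split demography and ms time scaling (population size 0.25, ploidy 2
# => pairwise coalescence rate 2 per time unit).

msprime_split_loci <- function(n_loci = 10000, t_join = 0.01833,
                               n1 = 40, n2 = 38, seed = 1) {
  py <- '
import sys
import numpy as np
import msprime

n_loci, t, n1, n2, seed = (int(sys.argv[1]), float(sys.argv[2]),
                           int(sys.argv[3]), int(sys.argv[4]),
                           int(sys.argv[5]))
dem = msprime.Demography()
dem.add_population(name="A", initial_size=0.25)
dem.add_population(name="B", initial_size=0.25)
dem.add_population(name="anc", initial_size=0.25)
dem.add_population_split(time=t, derived=["A", "B"], ancestral="anc")
rng = np.random.default_rng(seed)
reps = msprime.sim_ancestry(samples={"A": n1 // 2, "B": n2 // 2},
                            demography=dem, ploidy=2,
                            num_replicates=n_loci, random_seed=seed)
for ts in reps:
    tree = ts.first()
    nodes = [u for u in tree.nodes() if tree.parent(u) != -1]
    lens = np.array([tree.branch_length(u) for u in nodes])
    pick = nodes[rng.choice(len(nodes), p=lens / lens.sum())]
    der = np.zeros(ts.num_samples, dtype=int)
    for leaf in tree.leaves(pick):
        der[leaf] = 1
    a = der[:n1]
    b = der[n1:]
    h1 = int(np.sum(a[0::2] != a[1::2]))
    h2 = int(np.sum(b[0::2] != b[1::2]))
    print(int(a.sum()), int(b.sum()), h1, h2)
'
  f <- tempfile(fileext = ".py")
  writeLines(py, f)
  out <- system2("python", args = c(f, n_loci, t_join, n1, n2, seed),
                 stdout = TRUE)
  m <- do.call(rbind, lapply(strsplit(out, " "), as.integer))
  data.frame(d1 = m[, 1], d2 = m[, 2], het1 = m[, 3], het2 = m[, 4])
}
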