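"""Neutral coalescent samples in Hudson ms format.

Simulates equilibrium neutral samples (panmictic or symmetric two-deme
island model, haploid lineages, infinite-sites mutations on a continuous
genome) and prints them as ms-dialect text. Region-wide mutation and
recombination rates are per transmitted chromosome per generation, as in
the forward simulator; sizes are haploid chromosome counts.
"""

import argparse
import sys

import msprime


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--n1", type=int, required=True)
    ap.add_argument("--n2", type=int, default=0)
    ap.add_argument("--ne", type=float, required=True,
                    help="haploid size per deme (or total when panmictic)")
    ap.add_argument("--nm", type=float, default=0.0)
    ap.add_argument("--mu-region", type=float, default=0.006)
    ap.add_argument("--rho-region", type=float, default=0.006)
    ap.add_argument("--length", type=float, default=600000.0)
    ap.add_argument("--reps", type=int, default=1)
    ap.add_argument("--seed", type=int, required=True)
    a = ap.parse_args()

    two_demes = a.n2 > 0
    dem = msprime.Demography()
    if two_demes:
        dem.add_population(name="d1", initial_size=a.ne)
        dem.add_population(name="d2", initial_size=a.ne)
        m = a.nm / a.ne
        dem.set_symmetric_migration_rate(["d1", "d2"], m)
        samples = [msprime.SampleSet(a.n1, population="d1", ploidy=1),
                   msprime.SampleSet(a.n2, population="d2", ploidy=1)]
    else:
        dem.add_population(name="d1", initial_size=a.ne)
        samples = [msprime.SampleSet(a.n1, population="d1", ploidy=1)]

    n_tot = a.n1 + a.n2
    print(f"ms {n_tot} {a.reps}")
    print(f"{a.seed} 0 0")
    reps = msprime.sim_ancestry(
        samples=samples, demography=dem, ploidy=1,
        sequence_length=a.length,
        recombination_rate=a.rho_region / a.length,
        discrete_genome=False, num_replicates=a.reps,
        random_seed=a.seed)
    for i, ts in enumerate(reps):
        mts = msprime.sim_mutations(
            ts, rate=a.mu_region / a.length,
            model=msprime.BinaryMutationModel(),
            discrete_genome=False, random_seed=a.seed + 100003 * (i + 1))
        print("")
        print("//")
        print(f"segsites: {mts.num_sites}")
        if mts.num_sites > 0:
            pos = [s.position / a.length for s in mts.sites()]
            print("positions: " + " ".join(f"{p:.10f}" for p in pos))
            G = mts.genotype_matrix()  # sites x samples
            for j in range(n_tot):
                sys.stdout.write("".join(
                    "1" if G[k, j] > 0 else "0" for k in range(mts.num_sites)))
                sys.stdout.write("\n")


if __name__ == "__main__":
    main()
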