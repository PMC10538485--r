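"""Coalescent simulation helper: one diploid, truth TMRCA path + het sites.

Writes <prefix>_truth.tsv (start, end, tmrca_gen; 1-based inclusive bp) and
<prefix>_hets.txt (1-based positions, one per line).
"""

import argparse
import math

import msprime


def ooa_demography():
    """Three-population out-of-Africa model (Gutenkunst et al. 2009).

    Times in generations (25 yr generation time in the source publication),
    sizes in diploids, migration per generation.
    """
    T_ANC = 220e3 / 25
    T_AMH = 140e3 / 25
    T_OOA = 21.2e3 / 25
    r_EU = 0.004
    r_AS = 0.0055
    N_ANC = 7300
    N_AMH = 12300
    N_OOA = 2100
    N_EU0 = 1000
    N_AS0 = 510
    N_EU = N_EU0 * math.exp(r_EU * T_OOA)
    N_AS = N_AS0 * math.exp(r_AS * T_OOA)
    dem = msprime.Demography()
    dem.add_population(name="YRI", initial_size=N_AMH)
    dem.add_population(name="EUR", initial_size=N_EU, growth_rate=r_EU)
    dem.add_population(name="CHB", initial_size=N_AS, growth_rate=r_AS)
    dem.add_population(name="OOA", initial_size=N_OOA)
    dem.add_population(name="AMH", initial_size=N_AMH)
    dem.add_population(name="ANC", initial_size=N_ANC)
    dem.set_symmetric_migration_rate(["YRI", "EUR"], 3e-5)
    dem.set_symmetric_migration_rate(["YRI", "CHB"], 1.9e-5)
    dem.set_symmetric_migration_rate(["EUR", "CHB"], 9.6e-5)
    dem.add_population_split(time=T_OOA, derived=["EUR", "CHB"], ancestral="OOA")
    dem.add_symmetric_migration_rate_change(
        time=T_OOA, populations=["YRI", "OOA"], rate=25e-5
    )
    dem.add_population_split(time=T_AMH, derived=["YRI", "OOA"], ancestral="AMH")
    dem.add_population_split(time=T_ANC, derived=["AMH"], ancestral="ANC")
    dem.sort_events()
    return dem


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--model", choices=["constant", "ooa_ceu"], default="constant")
    ap.add_argument("--length", type=float, required=True)
    ap.add_argument("--ne", type=float, default=15000)
    ap.add_argument("--mu", type=float, default=1.25e-8)
    ap.add_argument("--recomb", type=float, default=1e-8)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out-prefix", required=True)
    args = ap.parse_args()

    common = dict(
        sequence_length=int(args.length),
        recombination_rate=args.recomb,
        random_seed=args.seed,
        discrete_genome=True,
    )
    if args.model == "constant":
        ts = msprime.sim_ancestry(samples=1, population_size=args.ne, **common)
    else:
        ts = msprime.sim_ancestry(
            samples={"EUR": 1}, demography=ooa_demography(), **common
        )
    ts = msprime.sim_mutations(
        ts, rate=args.mu, random_seed=args.seed + 1,
        model=msprime.BinaryMutationModel(),
    )

    with open(args.out_prefix + "_truth.tsv", "w") as fh:
        fh.write("start\tend\ttmrca_gen\n")
        prev = None
        for tree in ts.trees():
            left, right = tree.interval
            t = tree.tmrca(0, 1)
            if prev is not None and prev[2] == t and prev[1] + 1 == int(left) + 1:
                prev = (prev[0], int(right), t)
            else:
                if prev is not None:
                    fh.write(f"{prev[0]}\t{prev[1]}\t{prev[2]:.10g}\n")
                prev = (int(left) + 1, int(right), t)
        if prev is not None:
            fh.write(f"{prev[0]}\t{prev[1]}\t{prev[2]:.10g}\n")

    hets = set()
    for var in ts.variants():
        g = var.genotypes
        if g[0] != g[1]:
            hets.add(int(var.site.position) + 1)
    with open(args.out_prefix + "_hets.txt", "w") as fh:
        for p in sorted(hets):
            fh.write(f"{p}\n")


if __name__ == "__main__":
    main()
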