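"""Coalescent simulation of diploid genomes with crossover + gene conversion.

Thin bridge used by rhogc::simulate_genomes(): simulates a neutral
constant-size population in msprime, overlays mutations, and writes the
0-based heterozygous-site positions of each diploid individual as TSV
(columns: individual, position). Only population-scaled parameters matter;
per-generation rates are derived from a reference diploid size Ne.
"""

import argparse
import json
import sys


def main() -> int:
    ap = argparse.ArgumentParser(description=__doc__)
    ap.add_argument("--theta", type=float, required=True,
                    help="4*Ne*mu per bp")
    ap.add_argument("--kappa", type=float, required=True,
                    help="4*Ne*c per bp (crossover)")
    ap.add_argument("--gamma", type=float, required=True,
                    help="4*Ne*g per bp (gene-conversion initiation)")
    ap.add_argument("--tract-mean", type=float, required=True,
                    help="mean gene-conversion tract length, bp")
    ap.add_argument("--sequence-length", type=float, required=True)
    ap.add_argument("--individuals", type=int, default=10)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--ne", type=float, default=1e4,
                    help="reference diploid population size")
    ap.add_argument("--mutation-model", default="finite_sites",
                    choices=["finite_sites", "infinite_alleles"])
    ap.add_argument("--out", required=True)
    ap.add_argument("--meta", default=None)
    args = ap.parse_args()

    try:
        import msprime
    except ImportError:
        sys.stderr.write("msprime is not importable\n")
        return 3

    mu = args.theta / (4.0 * args.ne)
    c = args.kappa / (4.0 * args.ne)
    g = args.gamma / (4.0 * args.ne)

    ts = msprime.sim_ancestry(
        samples=args.individuals,
        sequence_length=int(args.sequence_length),
        population_size=args.ne,
        recombination_rate=c,
        gene_conversion_rate=g,
        gene_conversion_tract_length=args.tract_mean,
        ploidy=2,
        random_seed=args.seed,
    )
    if args.mutation_model == "infinite_alleles":
        model = msprime.InfiniteAlleles()
    else:
        model = None  # engine default (finite sites, JC69)
    mts = msprime.sim_mutations(ts, rate=mu, random_seed=args.seed,
                                model=model)

    n_ind = args.individuals
    with open(args.out, "w") as fh:
        fh.write("individual\tposition\n")
        for var in mts.variants():
            geno = var.genotypes
            pos = int(var.site.position)
            for k in range(n_ind):
                if geno[2 * k] != geno[2 * k + 1]:
                    fh.write(f"{k + 1}\t{pos}\n")

    if args.meta:
        meta = {
            "engine": f"msprime {msprime.__version__}",
            "seed": args.seed,
            "mutation_model": args.mutation_model,
            "conversion": {
                "ne": args.ne, "mu": mu, "c": c, "g": g,
                "note": "theta=4*Ne*mu, kappa=4*Ne*c, gamma=4*Ne*g",
            },
            "n_sites": mts.num_sites,
        }
        with open(args.meta, "w") as fh:
            json.dump(meta, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
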