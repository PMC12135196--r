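# Small in-code fixtures shared across test files.

tiny_genome <- function(n_chromosomes = 2, markers_per_chromosome = 60,
                        qtn_per_chromosome = 15, ...) {
  genome_spec(n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              qtn_per_chromosome = qtn_per_chromosome, ...)
}

tiny_config <- function(n_generations = 3, selection = "gebv",
                        offspring = 240, n_sires = 5, n_dams = 40,
                        beta = 0.05, burn_in = 5, ...) {
  sim_config(genome = tiny_genome(...),
             traits = trait_architecture(beta = beta),
             scheme = selection_scheme(n_sires = n_sires, n_dams = n_dams,
                                       offspring_per_generation = offspring,
                                       n_generations = n_generations,
                                       selection_criterion = selection),
             burn_in = burn_in, burn_in_size = 120, burn_in_parents = 20)
}

# random genotype matrix under Hardy-Weinberg with given frequencies
hw_genotypes <- function(n, freqs, prefix = "id") {
  M <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n))
  rownames(M) <- sprintf("%s%04d", prefix, seq_len(n))
  M
}
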