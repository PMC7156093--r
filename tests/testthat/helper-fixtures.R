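# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

all_mechanisms <- c("unequal_recombination", "ltr_recombination", "mmej",
                    "sdmmej", "blunt", "tandem_duplication", "introgression",
                    "te_insertion_full_empty", "inversion",
                    "internal_deletion", "assembly_artifact")

# one event of every mechanism, two chromosomes
pair11 <- function() memo("pair11", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 120000,
                    event_specs = lapply(all_mechanisms, event_spec),
                    seed = 7)
  simulate_genome_pair(cfg)
})

report11 <- function() memo("report11", {
  p <- pair11()
  run_pipeline(p$genome_a, p$genome_b, p$config$te_library[[1]],
               te_annotation = p$te_annotation)
})

# six events per repair mechanism across six chromosomes
acc_pair <- function() memo("acc_pair", {
  cfg <- sim_config(n_chromosomes = 6, chromosome_length = 130000,
                    te_copies_per_chromosome = 4,
                    event_specs = mechanism_suite_specs(6), seed = 101)
  simulate_genome_pair(cfg)
})

acc_report <- function() memo("acc_report", {
  p <- acc_pair()
  run_pipeline(p$genome_a, p$genome_b, p$config$te_library[[1]],
               te_annotation = p$te_annotation)
})

mechanism_label_map <- c(
  unequal_recombination = "unequal_recombination",
  ltr_recombination = "ltr_recombination",
  mmej = "mmej",
  sdmmej = "sdmmej",
  blunt = "blunt_cnhej_or_ambiguous",
  tandem_duplication = "cnv_duplication",
  introgression = "introgression")

# locus windows around a truth event (generous, anchored in background)
truth_windows <- function(pair, i, pad = 2000) {
  tr <- pair$truth
  ch <- tr$chromosome[i]
  a1 <- max(1L, tr$del_start[i] - pad)
  a2 <- min(nchar(pair$genome_a[[ch]]), tr$del_end[i] + pad)
  b1 <- max(1L, tr$b_start[i] - pad)
  b2 <- min(nchar(pair$genome_b[[ch]]),
            tr$b_start[i] + tr$b_replacement_length[i] + pad)
  list(chrom = ch,
       locus_a = substr(pair$genome_a[[ch]], a1, a2),
       locus_b = substr(pair$genome_b[[ch]], b1, b2),
       a_offset = a1 - 1L, b_offset = b1 - 1L)
}

# match summary rows to a truth row by donor-coordinate overlap
summary_row_for <- function(report, truth_row) {
  s <- report$summary
  s[s$chromosome == truth_row$chromosome &
      s$a_start <= truth_row$a_end + 10 &
      s$a_end >= truth_row$a_start - 10, , drop = FALSE]
}
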