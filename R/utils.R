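# Deterministic 31-bit string hash (polynomial rolling hash mod the
# Mersenne prime 2^31 - 1). Used to derive per-gene RNG sub-streams and
# config fingerprints; stable across platforms since only double-precision
# integer arithmetic below 2^53 is involved.
string_hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# Sub-seed for one gene's random stream within a cohort: mixes the cohort
# seed with the gene-name hash so streams are independent per gene and
# adding genes never perturbs existing ones.
gene_stream_seed <- function(seed, gene) {
  as.integer((string_hash31(gene) * 48271 + as.double(seed) * 16807 + 1) %%
               2147483647)
}

# Short hexadecimal fingerprint of an R object (deparsed, then hashed);
# recorded in output headers so runs with differing configs are
# distinguishable.
config_fingerprint <- function(x) {
  sprintf("%08x", string_hash31(paste(deparse(x), collapse = " ")))
}

# Standard provenance header lines for TSV outputs.
provenance_header <- function(config = NULL, seed = NULL) {
  c(sprintf("# tool=sigorder %s",
            as.character(utils::packageVersion("sigorder"))),
    if (!is.null(config))
      sprintf("# config_hash=%s", config_fingerprint(config)),
    if (!is.null(seed)) sprintf("# seed=%s", seed))
}
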