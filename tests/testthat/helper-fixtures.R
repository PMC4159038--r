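# Shared fixture builders: everything is generated in code at test time.

# mothur-dialect taxonomy summary text for a root + flat genus layer
make_tax_summary_text <- function(counts, genera, samples = colnames(counts)) {
  counts <- as.matrix(counts)
  colnames(counts) <- samples
  header <- paste(c("taxlevel", "rankID", "taxon", "daughterlevels", "total",
                    samples), collapse = "\t")
  root <- paste(c(0, "0", "Root", 1, sum(counts),
                  colSums(counts)), collapse = "\t")
  body <- vapply(seq_along(genera), function(i)
    paste(c(1, paste0("0.", i), genera[i], 0, sum(counts[i, ]),
            counts[i, ]), collapse = "\t"), "")
  c(header, root, body)
}

write_tax_summary_fixture <- function(counts, genera,
                                      samples = colnames(counts),
                                      path = tempfile(fileext = ".tax.summary")) {
  writeLines(make_tax_summary_text(counts, genera, samples), path)
  path
}

# the standard toy table used across modules: root 1000, two guild genera
toy_table <- function() {
  genus_matrix_table(data.frame(S1 = c(30, 20, 950)),
                     c("Alcanivorax", "Marinobacter", "OtherX"))
}

toy_guild <- function(genera = c("Alcanivorax", "Marinobacter"),
                      phylum = rep("Proteobacteria", length(genera))) {
  guild_definition(data.frame(genus = genera, phylum = phylum,
                              stringsAsFactors = FALSE))
}

# independent hypergeometric enumeration for the two-sided exact p,
# written from binomial coefficients only
fisher_p_enumeration <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  if (m == 0 || m == n1 + n2) return(1.0)
  support <- max(0, m - n2):min(n1, m)
  probs <- choose(n1, support) * choose(n2, m - support) / choose(n1 + n2, m)
  p_obs <- choose(n1, k1) * choose(n2, k2) / choose(n1 + n2, m)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# step-by-step transcription of the Wilson closed form, kept separate from
# the implementation
wilson_transcription <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  a <- phat + z * z / (2 * n)
  b <- z * sqrt(phat * (1 - phat) / n + (z / (2 * n))^2)
  c_ <- 1 + z * z / n
  c(max((a - b) / c_, 0), min((a + b) / c_, 1))
}

newcombe_transcription <- function(k1, n1, k2, n2, conf = 0.95) {
  w1 <- wilson_transcription(k1, n1, conf)
  w2 <- wilson_transcription(k2, n2, conf)
  p1 <- k1 / n1; p2 <- k2 / n2
  d <- p1 - p2
  c(max(d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2), -1),
    min(d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2), 1))
}
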