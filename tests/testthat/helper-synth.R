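# shared builders for synthetic test objects

# a minimal instrument set from raw vectors
mk_instr <- function(bx, by, sx = rep(0.01, length(bx)),
                     sy = rep(0.02, length(bx)), label = "test",
                     ids = sprintf("rs%03d", seq_along(bx))) {
  instrument_set(data.frame(snp_id = ids, beta_exp = bx, se_exp = sx,
                            beta_out = by, se_out = sy), label = label)
}

# a sumstats table from a compact spec; fills valid defaults
mk_sumstats <- function(n = 5, snp_id = sprintf("rs%03d", seq_len(n)),
                        beta = seq(0.05, by = 0.01, length.out = n),
                        se = rep(0.01, n), pval = NULL,
                        ea = rep("A", n), oa = rep("G", n),
                        eaf = rep(0.3, n), chrom = NA, pos = NA,
                        timepoint = NA, trait = "x", check_p = FALSE) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      effect_allele = ea, other_allele = oa, eaf = eaf,
                      beta = beta, se = se, pval = pval,
                      timepoint = timepoint),
           trait = trait, check_p = check_p)
}

# harmonised fixture instruments for one epoch, strict policy
fixture_instr <- function(epoch) {
  fx <- bmi_ms_instruments(epoch)
  harmonise(fx$exposure, fx$outcome)
}
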