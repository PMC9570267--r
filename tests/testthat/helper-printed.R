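# Published reference values used across tests, transcribed once here.

# Global reactivity descriptor table (eV; softness in 1/eV): the 7 usable
# compound/phase rows. Columns follow the descriptor_table() naming.
printed_descriptors <- function() {
  rows <- rbind(
    c(3.46, 6.46, 3.00, 4.73, 1.73, 0.29, -4.73, 6.47, -2.25),  # 2H gas
    c(3.36, 6.29, 2.94, 4.62, 1.68, 0.30, -4.62, 6.35, -2.08),  # 2H aqueous
    c(3.46, 6.76, 3.30, 5.03, 1.73, 0.29, -5.03, 7.31, -2.55),  # 6H gas
    c(3.22, 6.39, 3.16, 4.77, 1.61, 0.31, -4.77, 7.07, -2.18),  # 6H aqueous
    c(3.13, 6.09, 2.96, 4.53, 1.57, 0.32, -4.53, 6.54, -1.88),  # 7H gas
    c(3.28, 6.20, 2.92, 4.56, 1.64, 0.30, -4.56, 6.34, -1.99),  # 7H aqueous
    c(2.55, 5.44, 2.90, 4.17, 1.27, 0.39, -4.17, 6.83, -1.23)   # 9H aqueous
  )
  colnames(rows) <- c("e_gap", "i_pot", "e_aff", "chi", "eta", "s_soft",
                      "v_pot", "omega", "n_nuc")
  data.frame(compound = c("2H", "2H", "6H", "6H", "7H", "7H", "9H"),
             phase = c("gas", "aqueous", "gas", "aqueous", "gas", "aqueous",
                       "aqueous"),
             rows, stringsAsFactors = FALSE)
}

# Published A% row of the bond-length benchmark, by method column.
printed_a_percent <- function() {
  c("HF/6-311++G(d,p)"    = 1.386,
    "MP2/6-311++G(d,p)"   = 1.200,
    "B3LYP/6-311++G(d,p)" = 1.102,
    "HF/cc-pVDZ"          = 1.192,
    "MP2/cc-pVDZ"         = 1.257,
    "B3LYP/cc-pVDZ"       = 1.105)
}
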