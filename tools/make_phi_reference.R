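#!/usr/bin/env Rscript
# Regenerates the frozen Phi reference fixtures under
# inst/extdata/phi_reference/. The TPMs are built by the package from seeded
# random networks and written to CSV at full precision; the reference phi and
# repertoire values are then computed by the independent Python
# implementation (tools/iit3_reference.py, numpy + scipy linprog). The test
# suite compares the installed package's engine against these frozen values;
# it never runs Python itself.
#
# Run from the repository root after installing the package:
#   Rscript tools/make_phi_reference.R

library(isingphi)

out_dir <- "inst/extdata/phi_reference"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

write_tpm_plain <- function(tpm, path) {
  m <- unclass(as.matrix(tpm))
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
}

cases <- data.frame()
temps3 <- c(0.3, 0.8, 1.5, 2.5, 4.0)
for (k in 1:50) {
  J <- generate_random_network(3, seed = 200 + k)
  T_ <- temps3[(k - 1) %% 5 + 1]
  tpm <- build_tpm(J, T_)
  id <- sprintf("n3_%02d", k)
  write_tpm_plain(tpm, file.path(out_dir, paste0(id, ".csv")))
  cases <- rbind(cases, data.frame(
    case_id = id, n = 3, net_seed = 200 + k, temperature = T_,
    state_code = (k * 3) %% 8,
    tpm_path = file.path(out_dir, paste0(id, ".csv"))))
}
temps4 <- c(0.5, 1.0, 1.8, 2.7, 3.6)
for (k in 1:10) {
  J <- generate_random_network(4, seed = 300 + k)
  T_ <- temps4[(k - 1) %% 5 + 1]
  tpm <- build_tpm(J, T_)
  id <- sprintf("n4_%02d", k)
  write_tpm_plain(tpm, file.path(out_dir, paste0(id, ".csv")))
  cases <- rbind(cases, data.frame(
    case_id = id, n = 4, net_seed = 300 + k, temperature = T_,
    state_code = (k * 5) %% 16,
    tpm_path = file.path(out_dir, paste0(id, ".csv"))))
}
write.csv(cases[, c("case_id", "tpm_path", "state_code")],
          file.path(out_dir, "phi_cases_input.csv"), row.names = FALSE)

# repertoire reference cases: two TPMs, both directions, assorted
# mechanisms/purviews
rep_cases <- data.frame()
add_rep <- function(df, id, tpm_id, state, dir, mech, pv) {
  rbind(df, data.frame(case_id = id,
                       tpm_path = file.path(out_dir, paste0(tpm_id, ".csv")),
                       state_code = state, direction = dir,
                       mechanism = paste(mech, collapse = ";"),
                       purview = paste(pv, collapse = ";")))
}
rep_cases <- add_rep(rep_cases, "r01", "n3_01", 5, "cause", 1, c(1, 2))
rep_cases <- add_rep(rep_cases, "r02", "n3_01", 5, "cause", c(1, 3), c(1, 2, 3))
rep_cases <- add_rep(rep_cases, "r03", "n3_01", 5, "effect", 2, c(1, 3))
rep_cases <- add_rep(rep_cases, "r04", "n3_01", 5, "effect", c(1, 2, 3), 3)
rep_cases <- add_rep(rep_cases, "r05", "n3_02", 2, "cause", c(2, 3), 2)
rep_cases <- add_rep(rep_cases, "r06", "n3_02", 2, "effect", c(1, 2), c(2, 3))
rep_cases <- add_rep(rep_cases, "r07", "n4_01", 9, "cause", c(1, 4), c(2, 3))
rep_cases <- add_rep(rep_cases, "r08", "n4_01", 9, "cause", c(1, 2, 3, 4), c(1, 2, 3, 4))
rep_cases <- add_rep(rep_cases, "r09", "n4_01", 9, "effect", c(2, 4), c(1, 2, 3, 4))
rep_cases <- add_rep(rep_cases, "r10", "n4_05", 12, "cause", 3, c(1, 2, 3, 4))
rep_cases <- add_rep(rep_cases, "r11", "n4_05", 12, "effect", c(1, 3), c(2, 4))
rep_cases <- add_rep(rep_cases, "r12", "n4_05", 12, "cause", c(2, 3), c(1, 4))
write.csv(rep_cases, file.path(out_dir, "repertoire_cases_input.csv"),
          row.names = FALSE)

message("running the independent oracle (this takes a while) ...")
status <- system2("python", c("tools/iit3_reference.py", "phi",
                              file.path(out_dir, "phi_cases_input.csv"),
                              file.path(out_dir, "phi_oracle_raw.csv")))
stopifnot(status == 0)
status <- system2("python", c("tools/iit3_reference.py", "repertoire",
                              file.path(out_dir, "repertoire_cases_input.csv"),
                              file.path(out_dir, "repertoire_reference.csv")))
stopifnot(status == 0)

oracle <- read.csv(file.path(out_dir, "phi_oracle_raw.csv"))
ref <- merge(cases, oracle, by = "case_id")
ref <- ref[order(ref$case_id),
           c("case_id", "n", "net_seed", "temperature", "state_code", "phi")]
write.csv(ref, file.path(out_dir, "phi_reference.csv"), row.names = FALSE)
file.remove(file.path(out_dir, "phi_oracle_raw.csv"),
            file.path(out_dir, "phi_cases_input.csv"))
message("wrote ", nrow(ref), " phi reference cases")
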