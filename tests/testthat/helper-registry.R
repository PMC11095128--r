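# Shared fixture builders: everything is generated in code, nothing on disk.

pd_profile <- function(id = "A", volume = 50, p_severe = 0.3,
                       p_death_given_severe = 0.1,
                       p_death_given_not_severe = 0.01,
                       p_readmission = 0.1, p_popf_bc = 0.15,
                       p_reoperation = 0.05, los_median = 7, los_size = 4) {
  hospital_profile(id, "PD", volume, p_severe, p_death_given_severe,
                   p_death_given_not_severe, p_readmission,
                   p_popf_bc = p_popf_bc, p_reoperation = p_reoperation,
                   los_median = los_median, los_size = los_size)
}

liver_profile <- function(id = "A", procedure = "MINOR_LR", volume = 50,
                          p_severe = 0.1, p_death_given_severe = 0.05,
                          p_death_given_not_severe = 0.001,
                          p_readmission = 0.08, p_margin_adequate = 0.95,
                          los_median = 6, los_size = 8) {
  hospital_profile(id, procedure, volume, p_severe, p_death_given_severe,
                   p_death_given_not_severe, p_readmission,
                   p_margin_adequate = p_margin_adequate,
                   los_median = los_median, los_size = los_size)
}

# hand-built registry rows with explicit outcomes (defaults all favourable)
make_records <- function(n, hospital_id = "A", procedure = "PD",
                         year = 2021L, severe = FALSE, death = FALSE,
                         readmission = FALSE, los = 5L,
                         margin = NA, popf = FALSE, reop = FALSE) {
  liver <- procedure %in% c("MINOR_LR", "MAJOR_LR")
  data.frame(
    hospital_id = rep_len(hospital_id, n), year = rep_len(year, n),
    procedure = rep_len(procedure, n),
    tumour_type = rep_len(if (liver) "CRLM" else NA_character_, n),
    cd_grade_3a_plus = rep_len(severe, n), death = rep_len(death, n),
    readmission = rep_len(readmission, n),
    los_days = as.integer(rep_len(los, n)),
    margin_adequate = if (liver) rep_len(ifelse(is.na(margin), TRUE, margin), n)
      else rep_len(NA, n),
    popf_bc = if (liver) rep_len(NA, n) else rep_len(popf, n),
    reoperation = if (liver) rep_len(NA, n) else rep_len(reop, n))
}

strip_rows <- function(d) {
  rownames(d) <- NULL
  d
}
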