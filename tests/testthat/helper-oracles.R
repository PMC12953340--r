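# Independent oracles and small fixture builders used across the suite.

# Exhaustive-permutation Mann-Whitney: enumerate every assignment of the
# pooled observations to the two groups and count arrangements at least as
# extreme. Independent of wilcox.test / the package implementation.
brute_force_mw <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(x, y)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  switch(alternative,
    two_sided = min(1, 2 * min(p_le, p_ge)),
    less = p_le,
    greater = p_ge
  )
}

# Write a small wide-format sample CSV and return its path.
write_sample_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(rows, path)
  path
}

# A minimal all-point exposure scenario for deterministic checks.
point_scenario <- function(age_group = "child_2y",
                           IngR = 50, InhR = 10, ExpF = 365, ED = 6,
                           BW = 15, SA = 2800, AF = 0.2, ABS = 0.001,
                           PEF = 1.36e9, CF = 1e-6, at_ca = 70 * 365) {
  exposure_scenario(
    age_group = age_group,
    params = list(
      IngR = dist_point(IngR), InhR = dist_point(InhR),
      ExpF = dist_point(ExpF), ED = dist_point(ED),
      BW = dist_point(BW), SA = dist_point(SA),
      AF = dist_point(AF), ABS = dist_point(ABS),
      PEF = dist_point(PEF), CF = dist_point(CF)
    ),
    at_ca = dist_point(at_ca)
  )
}

# Deterministic HI/TCR from the dose/risk primitives, composed in the same
# metal-within-route order the engine documents.
deterministic_risk <- function(conc_values, scen_pars, toxicity,
                               at_nc, at_ca) {
  routes <- c("ingestion", "dermal", "inhalation")
  dose_fun <- list(
    ingestion = add_ingestion, dermal = add_dermal, inhalation = add_inhalation
  )
  p_nc <- c(scen_pars, list(AT = at_nc))
  p_ca <- c(scen_pars, list(AT = at_ca))
  hq <- c(); cr <- c()
  for (route in routes) {
    for (m in names(conc_values)) {
      row <- toxicity[toxicity$metal == m, ]
      rfd <- row[[paste0("rfd_", route)]]
      if (!is.na(rfd)) {
        hq <- c(hq, hazard_quotient(dose_fun[[route]](conc_values[[m]], p_nc), rfd))
      }
      sf <- row[[paste0("sf_", route)]]
      if (!is.na(sf)) {
        cr <- c(cr, cancer_risk(dose_fun[[route]](conc_values[[m]], p_ca), sf))
      }
    }
  }
  list(hi = hazard_index(hq), tcr = total_cancer_risk(cr))
}
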