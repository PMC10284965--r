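# shared fixtures, built once per test run

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# coarse grid for fast registration/landmarking tests
coarse_params <- function(cleft_type = "UCLP", ...) {
  palate_params(cleft_type, n_arc = 36, n_rad = 14, ...)
}

fix_template <- function() {
  fixture("tpl_uclp", generate_template("UCLP", n_samples = 5, seed = 1))
}

fix_template_coarse <- function() {
  fixture("tpl_uclp_coarse",
          generate_template("UCLP", n_samples = 3, seed = 1,
                            params = coarse_params()))
}

fix_scan7 <- function() {
  fixture("scan_uclp_7", generate_palate(palate_params("UCLP", seed = 7)))
}

fix_fit7 <- function() {
  fixture("fit_uclp_7", compute_plate(fix_scan7(), fix_template()))
}

fix_suite10 <- function() {
  fixture("suite10",
          evaluate_fixture_suite(n_seeds = 10, cleft_type = "UCLP",
                                 template = fix_template()))
}

# registration fixture with known dense correspondence
fix_regpair <- function() {
  fixture("regpair", {
    tpl <- fix_template()
    scan <- make_scan_from_template(tpl, deform_magnitude = 3,
                                    noise_sd = 0, seed = 4)
    lm <- scan$landmarks
    lm$probabilities <- rep(1, 10)
    list(template = tpl, scan = scan,
         registered = staged_register(tpl, scan$mesh, landmarks = lm))
  })
}
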