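# One shared end-to-end run of the frozen study fixture; the acceptance and
# pipeline tests read from it instead of regenerating per test.
study_dir <- file.path(tempdir(), "nshl-study-fixture")
study_gen <- generate_cohort(study_fixture_config(), study_dir)
study_run <- run_screen(study_gen$run_config)
study_glance <- glance(study_run)
withr::defer(unlink(study_dir, recursive = TRUE), teardown_env())
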