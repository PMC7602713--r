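make_member_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  helix <- build_backbone(24, "ideal_helix")
  write_pdb(helix, file.path(dir, "helix.pdb"))
  write_fasta(adaptsig:::new_sequence_record("seqonly", strrep("DEKRGASTNQ", 12)),
              file.path(dir, "seqonly.fasta"))
  b <- make_trajectory(synth_traj_spec(n_residues = 24, frames_per_window = 40,
                                       seed = 4))
  write_trajectory(b$trajectory, file.path(dir, "traj1.pdb"))
  b2 <- make_trajectory(synth_traj_spec(n_residues = 24, frames_per_window = 40,
                                        seed = 5))
  write_trajectory(b2$trajectory, file.path(dir, "traj2.pdb"))
  list(helix = file.path(dir, "helix.pdb"),
       fasta = file.path(dir, "seqonly.fasta"),
       traj = file.path(dir, c("traj1.pdb", "traj2.pdb")),
       schedule = window_schedule(c(1, 41, 81, 121), c(40, 80, 120, 160),
                                  c(10, 27, 47, 72), 0.5))
}

test_that("members lacking inputs get NA cells, not an abort", {
  fx <- make_member_files(tempfile())
  cfg <- compare_config(
    groups = list(g1 = list(list(label = "seqonly", sequence = fx$fasta)),
                  g2 = list(list(label = "helix", structure = fx$helix))),
    focal = "seqonly", n_points = 120)
  expect_warning(rep <- run_comparison(cfg), "unavailable")
  expect_true(is.na(rep$members["surf_negative", "seqonly"]))
  expect_false(is.na(rep$members["negative", "seqonly"]))
  expect_false(is.na(rep$members["helix", "helix"]))
  expect_true(is.na(rep$members["rmsd_slope", "helix"]))
})

test_that("two identical members average to the member value and ordering is irrelevant", {
  fx <- make_member_files(tempfile())
  mk <- function(lbls) compare_config(
    groups = list(g = lapply(lbls, function(l)
      list(label = l, structure = fx$helix)),
      solo = list(list(label = "solo", structure = fx$helix))),
    focal = "solo", n_points = 120)
  r1 <- suppressWarnings(run_comparison(mk(c("a", "b"))))
  expect_equal(r1$groups[["g"]], r1$members[["a"]])
  r2 <- suppressWarnings(run_comparison(mk(c("b", "a"))))
  expect_equal(r1$groups[["g"]], r2$groups[["g"]])
})

test_that("trajectory members get regression metrics through the config schedule", {
  fx <- make_member_files(tempfile())
  cfg <- compare_config(
    groups = list(g = list(list(label = "dyn", structure = fx$helix,
                                trajectories = fx$traj))),
    focal = "dyn", n_points = 120, schedule = fx$schedule)
  rep <- suppressWarnings(run_comparison(cfg))
  expect_false(is.na(rep$members["rmsd_slope", "dyn"]))
  expect_gt(rep$members["rmsd_slope", "dyn"], 0)
  expect_lte(rep$members["rmsd_r2", "dyn"], 1)
})

test_that("reports render deterministically with one row per label", {
  fx <- make_member_files(tempfile())
  cfg <- compare_config(
    groups = list(g = list(list(label = "m", structure = fx$helix))),
    focal = "m", n_points = 120)
  rep <- suppressWarnings(run_comparison(cfg))
  out1 <- tempfile(); out2 <- tempfile()
  render_report(rep, out1); render_report(rep, out2)
  tsv1 <- readLines(file.path(out1, "members.tsv"))
  expect_identical(tsv1, readLines(file.path(out2, "members.tsv")))
  expect_equal(length(tsv1), length(adaptsig:::METRIC_LABELS) + 1L)
  back <- read_report_json(file.path(out1, "report.json"))
  expect_equal(back$members, rep$members)
  expect_equal(back$focal, rep$focal)
})

test_that("YAML configs resolve relative paths and schedules", {
  fx <- make_member_files(d <- tempfile())
  yml <- file.path(d, "cfg.yaml")
  writeLines(c(
    "focal: m",
    "n_points: 120",
    "schedule:",
    "  start: [1, 41, 81, 121]",
    "  end: [40, 80, 120, 160]",
    "  temperature_C: [10, 27, 47, 72]",
    "  analysis_fraction: 0.5",
    "groups:",
    "  g:",
    "    - label: m",
    "      structure: helix.pdb",
    paste0("      trajectories: [traj1.pdb, traj2.pdb]")), yml)
  cfg <- read_compare_config(yml)
  expect_s3_class(cfg, "compare_config")
  expect_equal(nrow(cfg$schedule), 4L)
  rep <- suppressWarnings(run_comparison(cfg))
  expect_false(is.na(rep$members["rmsd_slope", "m"]))
})

test_that("config validation catches missing files and bad focal members", {
  expect_error(compare_config(
    groups = list(g = list(list(label = "x", sequence = "/no/such.fasta"))),
    focal = "x"), "missing file")
  fx <- make_member_files(tempfile())
  expect_error(compare_config(
    groups = list(g = list(list(label = "x", structure = fx$helix))),
    focal = "nope"), "focal")
  expect_error(compare_config(
    groups = list(g = list(list(label = "x", structure = fx$helix),
                           list(label = "x", structure = fx$helix))),
    focal = "x"), "duplicate")
})

test_that("the CLI dispatches, writes JSON and signals bad usage", {
  d <- tempfile(); dir.create(d)
  fx <- make_member_files(d)
  out <- file.path(d, "seq.json")
  expect_equal(suppressMessages(cli_main(c("seq", fx$fasta, out))), 0L)
  j <- jsonlite::read_json(out, simplifyVector = FALSE)
  expect_equal(j[[1]]$id, "seqonly")
  expect_equal(j[[1]]$n, 120L)
  expect_equal(suppressMessages(cli_main("nope")), 2L)
  expect_equal(suppressMessages(cli_main(c("seq", "/no/such.fasta"))), 1L)
})
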