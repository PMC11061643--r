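test_that("the behaviour vocabulary partitions into predator acts and escape patterns", {
  labs <- behaviour_labels()
  expect_length(labs, 12)
  expect_setequal(labs, c(predator_acts(), escape_patterns()))
  # each label belongs to exactly one class
  expect_true(all(xor(is_predator_act(labs), is_escape_pattern(labs))))
  expect_false(is_escape_pattern("soaring"))
})

test_that("event logs round-trip through CSV and reject bad rows", {
  ev <- toy_events("c1", c(0, 2.5, 7), c("attack", "Flash Expansion", "split"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$behaviour, c("attack", "flash_expansion", "split"))
  expect_equal(back$t_onset_s, c(0, 2.5, 7))

  # canonical form is a fixed point: write(read(f)) is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_events(back, f2)
  write_events(read_events(f2), f)
  expect_identical(readBin(f, "raw", file.size(f)), readBin(f2, "raw", file.size(f2)))

  # header-only file: empty result, no error
  writeLines("chase_id,t_onset_s,actor,behaviour", f)
  expect_equal(nrow(read_events(f)), 0)

  # unknown behaviour label names the offending row
  writeLines(c("chase_id,t_onset_s,actor,behaviour",
               "c1,0,flock,split", "c1,3,flock,soaring"), f)
  expect_error(read_events(f), "soaring.*row 2|row 2.*soaring")
  # malformed time
  writeLines(c("chase_id,t_onset_s,actor,behaviour", "c1,abc,flock,split"), f)
  expect_error(read_events(f), "time")
})

test_that("chase metadata parsing validates ranges, duplicates and defaults", {
  ch <- rbind(toy_chase("c1"), toy_chase("c2", species = "gulls"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_chases(ch, f)
  back <- read_chases(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$species, c("starlings", "gulls"))
  expect_identical(back$multiple_species, c(FALSE, FALSE))

  bad <- toy_chase("c1", chasing_intensity = 1.2)
  write_chases(bad, f)
  expect_error(read_chases(f), "chasing_intensity")

  dup <- rbind(toy_chase("c1"), toy_chase("c1"))
  write_chases(dup, f)
  expect_error(read_chases(f), "duplicate")

  # blank altitude on a drone chase defaults to unknown
  writeLines(c("chase_id,species,predator_type,duration_s,chasing_intensity,altitude_class,multiple_species,operator_id,flock_size",
               "d1,gulls,drone,120,0.4,,false,op1,"), f)
  expect_equal(read_chases(f)$altitude_class, "unknown")
})

test_that("BORIS-style exports map onto the canonical schema with inferred actors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Observation.id,Time,Behavior",
               "obs1,0.0,attack", "obs1,2.0,compacting", "obs2,1.5,split"), f)
  ev <- read_events_boris(f)
  expect_equal(ev$actor, c("predator", "flock", "flock"))
  expect_equal(ev$chase_id, c("obs1", "obs1", "obs2"))
})

test_that("cross-validation reports orphans, late onsets and actor mismatches", {
  ch <- toy_chase("c1", duration_s = 60)
  ok <- toy_events("c1", c(1, 5), c("attack", "split"))
  expect_equal(nrow(validate_dataset(ok, ch)), 0)

  ev <- rbind(ok,
              toy_events("ghost", 1, "split"),
              toy_events("c1", 80, "compacting"),
              data.frame(chase_id = "c1", t_onset_s = 3, actor = "flock",
                         behaviour = "attack", stringsAsFactors = FALSE))
  rep <- validate_dataset(ev, ch)
  expect_setequal(rep$finding,
                  c("unknown_chase", "onset_after_end", "actor_label_mismatch"))
  expect_equal(sum(rep$finding == "onset_after_end"), 1)
})

test_that("per-chase escape counts and per-minute rates match a hand tally", {
  ch <- rbind(toy_chase("c1", duration_s = 120), toy_chase("c2", duration_s = 60))
  # 6 escapes in c1 (plus predator events that must not count), 4 in c2
  ev <- rbind(toy_events("c1", seq(1, 110, length.out = 6), rep("collective_turn", 6)),
              toy_events("c1", c(2, 50), rep("attack", 2)),
              toy_events("c2", c(3, 9, 20, 44), c("split", "merge", "compacting", "split")))
  tab <- escape_counts_per_chase(ev, ch)
  expect_equal(tab$n_escapes[tab$chase_id == "c1"], 6L)
  expect_equal(tab$rate_per_min[tab$chase_id == "c1"], 3.0)
  expect_equal(tab$n_escapes[tab$chase_id == "c2"], 4L)

  # a chase with only predator events appears with count zero
  ch3 <- rbind(ch, toy_chase("c3", duration_s = 30))
  ev3 <- rbind(ev, toy_events("c3", 5, "pursuit"))
  tab3 <- escape_counts_per_chase(ev3, ch3)
  expect_equal(tab3$n_escapes[tab3$chase_id == "c3"], 0L)
  expect_equal(tab3$rate_per_min[tab3$chase_id == "c3"], 0)
})

test_that("dataset summary totals equal the sum of their per-species cells", {
  fx <- table2_fixture()
  s <- summarize_dataset(fx$events, fx$chases)
  for (pt in unique(s$predator_type)) {
    cells <- s[s$predator_type == pt & s$species != "total", ]
    tot <- s[s$predator_type == pt & s$species == "total", ]
    expect_equal(tot$n_chases, sum(cells$n_chases))
    expect_equal(tot$n_escape_events, sum(cells$n_escape_events))
  }
  # single chase: s.e. of duration is reported as absent, not zero
  one <- toy_chase("solo")
  s1 <- summarize_dataset(toy_events("solo", 1, "split"), one)
  expect_true(is.na(s1$se_duration_s[s1$species == "starlings"]))
})

test_that("escape-type composition weights chases equally and sums to 100 within chase", {
  # one chase: 2 turns, 1 compacting, 1 split -> 50/25/25
  ch <- toy_chase("c1")
  ev <- toy_events("c1", 1:4, c("collective_turn", "collective_turn", "compacting", "split"))
  comp <- escape_type_composition(ev, ch, grouping = "species")
  expect_equal(comp$mean_pct[comp$behaviour == "collective_turn"], 50)
  expect_equal(comp$mean_pct[comp$behaviour == "compacting"], 25)
  expect_equal(comp$mean_pct[comp$behaviour == "split"], 25)
  expect_equal(sum(comp$mean_pct), 100, tolerance = 1e-9)

  # equal chase weighting: chase A all turns (2 events), chase B no turns
  # (4 events) -> mean turn share 50% regardless of event counts
  ch2 <- rbind(toy_chase("a"), toy_chase("b"))
  ev2 <- rbind(toy_events("a", c(1, 2), rep("collective_turn", 2)),
               toy_events("b", 1:4, rep("split", 4)))
  comp2 <- escape_type_composition(ev2, ch2, grouping = "species")
  expect_equal(comp2$mean_pct[comp2$behaviour == "collective_turn"], 50)

  # chases without escape events are excluded and reported
  ch3 <- rbind(ch2, toy_chase("empty"))
  ev3 <- rbind(ev2, toy_events("empty", 1, "attack"))
  expect_warning(comp3 <- escape_type_composition(ev3, ch3, grouping = "species"),
                 "excluded")
  expect_equal(attr(comp3, "excluded_chases"), "empty")
  expect_equal(unique(comp3$n_chases), 2)
})

test_that("per-chase composition sums to 100 for every chase of a simulated dataset", {
  sim <- simulate_dataset(seed = 202)
  esc <- sim$events[sim$events$actor == "flock", ]
  per <- split(esc$behaviour, esc$chase_id)
  for (b in per) {
    pct <- 100 * table(factor(b, levels = escape_patterns())) / length(b)
    expect_equal(sum(pct), 100, tolerance = 1e-9)
  }
  # sum of per-chase counts equals the summary grand totals
  s <- summarize_dataset(sim$events, sim$chases)
  counts <- escape_counts_per_chase(sim$events, sim$chases)
  expect_equal(sum(s$n_escape_events[s$species == "total"]), sum(counts$n_escapes))
})
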