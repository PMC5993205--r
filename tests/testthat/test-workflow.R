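test_that("workflow graphs persist and reload identically", {
  counting_entry()
  g <- wf_graph(list(wf_module("A", "acquisition", "test_count"),
                     wf_module("B", "compute", "test_count", list(k = 2)),
                     wf_module("C", "compute", "test_count")),
                data.frame(parent = c("A", "B"), child = c("B", "C")),
                list(main = "A"))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  st2 <- wf_store(st$path)
  g2 <- wf_load_graph(st2, wid)
  expect_equal(scopeflow:::graph_to_list(g2), scopeflow:::graph_to_list(g))

  empty <- wf_graph(list(wf_module("solo", "compute", "test_count")))
  wid2 <- wf_persist(empty, st)
  expect_equal(length(wf_load_graph(wf_store(st$path), wid2)$modules), 1)
})

test_that("invalid graphs are rejected with informative errors", {
  counting_entry()
  mods <- list(wf_module("A", "compute", "test_count"),
               wf_module("B", "compute", "test_count"),
               wf_module("C", "compute", "test_count"))
  err <- tryCatch(
    wf_graph(mods, data.frame(parent = c("A", "B", "C"), child = c("B", "C", "A"))),
    error = function(e) e)
  expect_s3_class(err, "sf_workflow_error")
  expect_match(conditionMessage(err), "cycle")
  expect_error(wf_graph(mods, data.frame(parent = "A", child = "missing")),
               class = "sf_workflow_error")
})

test_that("a chain executes in order and re-dispatch is idempotent", {
  counting_entry()
  counts <- new.env(); counts$n <- list()
  g <- wf_graph(list(wf_module("A", "acquisition", "test_count"),
                     wf_module("B", "compute", "test_count"),
                     wf_module("C", "compute", "test_count")),
                data.frame(parent = c("A", "B"), child = c("B", "C")),
                list(main = "A"))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  rl <- wf_dispatch(st, wid, "main", c("s1", "s2"), workers = 4,
                    ctx = list(counts = counts))
  expect_equal(as.integer(rl$summary["SUCCESS"]), 6)
  # edge order respected in the recorded schedule
  sch <- rl$schedule
  for (s in c("s1", "s2")) {
    tt <- wf_tasks(st); tt <- tt[tt$slide_id == s, ]
    waves <- sch$wave[match(tt$task_id[match(c("A", "B", "C"), tt$module)],
                            sch$task_id)]
    expect_true(all(diff(waves) > 0))
  }
  expect_true(all(unlist(counts$n) == 1))
  wf_dispatch(st, wid, "main", c("s1", "s2"), ctx = list(counts = counts))
  expect_true(all(unlist(counts$n) == 1))   # completed tasks never re-execute
})

test_that("a failing task isolates its descendants but not other branches", {
  counting_entry()
  counts <- new.env(); counts$n <- list()
  g <- wf_graph(list(wf_module("A", "compute", "test_fail"),
                     wf_module("B", "compute", "test_count"),
                     wf_module("D", "compute", "test_count"),
                     wf_module("C", "compute", "test_count")),
                data.frame(parent = c("A", "B"), child = c("B", "D")),
                list(main = c("A", "C")))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  rl <- wf_dispatch(st, wid, "main", "s1", ctx = list(counts = counts))
  tt <- wf_tasks(st)
  expect_equal(tt$status[tt$module == "A"], "ERROR")
  expect_equal(tt$status[tt$module == "B"], "NEW")
  expect_equal(tt$status[tt$module == "D"], "NEW")
  expect_equal(tt$status[tt$module == "C"], "SUCCESS")
})

test_that("interrupted runs resume without repeating completed work", {
  counting_entry()
  counts <- new.env(); counts$n <- list()
  g <- wf_graph(list(wf_module("A", "acquisition", "test_count"),
                     wf_module("B", "compute", "test_count"),
                     wf_module("C", "compute", "test_count")),
                data.frame(parent = c("A", "B"), child = c("B", "C")),
                list(main = "A"))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  r1 <- wf_dispatch(st, wid, "main", "sX",
                    ctx = list(counts = counts, interrupt_after = 1))
  expect_true(r1$interrupted)
  expect_equal(sort(wf_tasks(st)$status), c("NEW", "NEW", "SUCCESS"))
  st2 <- wf_store(st$path)       # fresh process view
  r2 <- wf_resume(st2, wid, "main", "sX", ctx = list(counts = counts))
  expect_equal(unique(wf_tasks(st2)$status), "SUCCESS")
  expect_true(all(unlist(counts$n) == 1))   # tasks 2 and 3 ran exactly once

  # resuming a complete run executes nothing
  r3 <- wf_resume(wf_store(st$path), wid, "main", "sX", ctx = list(counts = counts))
  expect_true(all(unlist(counts$n) == 1))
})

test_that("stale IN_PROGRESS tasks from a dead run are reset and re-run", {
  killed <- new.env(); killed$done <- FALSE
  register_module_entry("test_kill_once", function(task, ctx) {
    if (!ctx$flag$done) { ctx$flag$done <- TRUE; sf_interrupt() }
    list(status = "SUCCESS")
  })
  g <- wf_graph(list(wf_module("A", "acquisition", "test_kill_once")),
                entry_points = list(main = "A"))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  r1 <- wf_dispatch(st, wid, "main", "s1", ctx = list(flag = killed))
  expect_equal(wf_tasks(st)$status, "IN_PROGRESS")   # crashed mid-task
  st2 <- wf_store(st$path)
  r2 <- wf_resume(st2, wid, "main", "s1", ctx = list(flag = killed))
  expect_equal(wf_tasks(st2)$status, "SUCCESS")
})

test_that("crash-resume reaches the uninterrupted SUCCESS set from any point", {
  counting_entry()
  g <- wf_graph(list(wf_module("acq", "acquisition", "test_count"),
                     wf_module("c1", "compute", "test_count"),
                     wf_module("c2", "compute", "test_count"),
                     wf_module("c3", "compute", "test_count")),
                data.frame(parent = c("acq", "acq", "c1"),
                           child = c("c1", "c2", "c3")),
                list(main = "acq"))
  baseline <- local({
    st <- wf_store(withr::local_tempdir())
    wid <- wf_persist(g, st)
    wf_dispatch(st, wid, "main", c("s1", "s2"),
                ctx = list(counts = new.env()))
    tt <- wf_tasks(st)
    sort(paste(tt$module, tt$slide_id)[tt$status == "SUCCESS"])
  })
  for (cut in 1:5) {
    st <- wf_store(withr::local_tempdir())
    wid <- wf_persist(g, st)
    counts <- new.env(); counts$n <- list()
    wf_dispatch(st, wid, "main", c("s1", "s2"),
                ctx = list(counts = counts, interrupt_after = cut))
    st2 <- wf_store(st$path)
    wf_resume(st2, wid, "main", c("s1", "s2"),
              ctx = list(counts = counts))
    tt <- wf_tasks(st2)
    expect_equal(sort(paste(tt$module, tt$slide_id)[tt$status == "SUCCESS"]),
                 baseline)
    expect_true(all(unlist(counts$n) == 1))
  }
})

test_that("the hardware lock serialises acquisition while compute overlaps", {
  counting_entry()
  g <- wf_graph(c(list(wf_module("acq1", "acquisition", "test_count"),
                       wf_module("acq2", "acquisition", "test_count")),
                  lapply(1:6, function(i)
                    wf_module(paste0("c", i), "compute", "test_count"))),
                data.frame(parent = rep("acq1", 6), child = paste0("c", 1:6)),
                list(main = c("acq1", "acq2")))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  rl <- wf_dispatch(st, wid, "main", "s1", workers = 4,
                    ctx = list(counts = new.env()))
  sch <- rl$schedule
  acq_per_wave <- tapply(sch$kind == "acquisition", sch$wave, sum)
  expect_true(all(acq_per_wave <= 1))
  cmp_per_wave <- tapply(sch$kind == "compute", sch$wave, sum)
  expect_gte(max(cmp_per_wave), 2)
})

test_that("deferred manual tasks park until acknowledged", {
  register_module_entry("test_manual", function(task, ctx) {
    if (isTRUE(task$acknowledged)) list(status = "SUCCESS")
    else list(status = "DEFER")
  })
  g <- wf_graph(list(wf_module("load", "acquisition", "test_manual")),
                entry_points = list(main = "load"))
  st <- wf_store(withr::local_tempdir())
  wid <- wf_persist(g, st)
  wf_dispatch(st, wid, "main", "s1")
  expect_equal(wf_tasks(st)$status, "DEFER")
  wf_acknowledge(st, wf_tasks(st)$task_id[1])
  wf_dispatch(st, wid, "main", "s1")
  expect_equal(wf_tasks(st)$status, "SUCCESS")
})

test_that("corrupt stores fail loudly", {
  d <- withr::local_tempdir()
  st <- wf_store(d)
  writeLines("{ not json", file.path(d, "store.json"))
  expect_error(wf_store(d), class = "sf_store_error")
})
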