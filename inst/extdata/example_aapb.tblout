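#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----
# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target
#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ -----   --- --- --- --- --- --- --- --- ---------------------
WP_000001.1          -          TIGR01289            -            1.2e-80  270.5   0.0   1.5e-80  270.1   0.0   1.0   1   0   0   1   1   1   1 protochlorophyllide reductase
WP_000002.1          -          TIGR02014            -            3.4e-95  312.0   0.0   4.0e-95  311.7   0.0   1.0   1   0   0   1   1   1   1 DPOR subunit B
WP_000003.1          -          TIGR02016            -            2.2e-88  280.3   0.0   2.8e-88  280.0   0.0   1.0   1   0   0   1   1   1   1 DPOR subunit L
WP_000004.1          -          TIGR02015            -            8.1e-90  290.8   0.0   9.9e-90  290.4   0.0   1.0   1   0   0   1   1   1   1 DPOR subunit N
WP_000005.1          -          TIGR01157            -            5.5e-70  230.2   0.1   6.3e-70  229.9   0.1   1.0   1   0   0   1   1   1   1 reaction center subunit L
WP_000006.1          -          TIGR01115            -            4.7e-72  236.6   0.0   5.5e-72  236.3   0.0   1.0   1   0   0   1   1   1   1 reaction center subunit M
WP_000007.1          -          TIGR02029            -            9.9e-75  248.9   0.0   1.2e-74  248.6   0.0   1.0   1   0   0   1   1   1   1 oxidative cyclase AcsF
WP_000008.1          -          PF00016              -            2.0e-03   15.2   0.0   2.6e-03   14.8   0.0   1.0   1   0   0   1   1   1   1 spurious RuBisCO-like hit below cutoff
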