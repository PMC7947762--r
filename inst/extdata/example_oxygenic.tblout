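# target name        accession  query name           accession    E-value  score  bias ...
WP_100001.1          -          PF00016              -            1.1e-120  400.1   0.0  1e-120 400.0 0.0 1.0 1 0 0 1 1 1 1 RuBisCO large subunit
WP_100002.1          -          PF00485              -            3.3e-90   295.5   0.0  4e-90  295.1 0.0 1.0 1 0 0 1 1 1 1 phosphoribulokinase
WP_100003.1          -          PF00421              -            1.2e-95   310.0   0.0  2e-95  309.6 0.0 1.0 1 0 0 1 1 1 1 photosystem II D1
WP_100004.1          -          PF00422              -            2.2e-93   305.2   0.0  3e-93  304.9 0.0 1.0 1 0 0 1 1 1 1 photosystem II D2
WP_100005.1          -          TIGR01289            -            5.0e-85   275.0   0.0  6e-85  274.6 0.0 1.0 1 0 0 1 1 1 1 protochlorophyllide reductase
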