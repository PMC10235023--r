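stage	sex	histology	sojourn_years
1	female	adenocarcinoma	2.86
2	female	adenocarcinoma	1.716
3	female	adenocarcinoma	1.287
4	female	adenocarcinoma	0.858
1	male	adenocarcinoma	2.6
2	male	adenocarcinoma	1.56
3	male	adenocarcinoma	1.17
4	male	adenocarcinoma	0.78
1	female	squamous	2.2
2	female	squamous	1.32
3	female	squamous	0.99
4	female	squamous	0.66
1	male	squamous	2
2	male	squamous	1.2
3	male	squamous	0.9
4	male	squamous	0.6
1	female	large_cell	1.98
2	female	large_cell	1.188
3	female	large_cell	0.891
4	female	large_cell	0.594
1	male	large_cell	1.8
2	male	large_cell	1.08
3	male	large_cell	0.81
4	male	large_cell	0.54
1	female	small_cell	1.1
2	female	small_cell	0.66
3	female	small_cell	0.495
4	female	small_cell	0.33
1	male	small_cell	1
2	male	small_cell	0.6
3	male	small_cell	0.45
4	male	small_cell	0.3
1	female	other	2.2
2	female	other	1.32
3	female	other	0.99
4	female	other	0.66
1	male	other	2
2	male	other	1.2
3	male	other	0.9
4	male	other	0.6
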