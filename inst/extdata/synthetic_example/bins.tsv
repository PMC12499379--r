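chrS	0	25000
chrS	25000	50000
chrS	50000	75000
chrS	75000	1e+05
chrS	1e+05	125000
chrS	125000	150000
chrS	150000	175000
chrS	175000	2e+05
chrS	2e+05	225000
chrS	225000	250000
chrS	250000	275000
chrS	275000	3e+05
chrS	3e+05	325000
chrS	325000	350000
chrS	350000	375000
chrS	375000	4e+05
chrS	4e+05	425000
chrS	425000	450000
chrS	450000	475000
chrS	475000	5e+05
chrS	5e+05	525000
chrS	525000	550000
chrS	550000	575000
chrS	575000	6e+05
chrS	6e+05	625000
chrS	625000	650000
chrS	650000	675000
chrS	675000	7e+05
chrS	7e+05	725000
chrS	725000	750000
chrS	750000	775000
chrS	775000	8e+05
chrS	8e+05	825000
chrS	825000	850000
chrS	850000	875000
chrS	875000	9e+05
chrS	9e+05	925000
chrS	925000	950000
chrS	950000	975000
chrS	975000	1e+06
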