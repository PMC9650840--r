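#gene_id	start	end
g0001	0	999
g0002	999	1998
g0003	1998	2997
g0004	2997	3996
g0005	3996	4995
g0006	4995	5994
g0007	5994	6000
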