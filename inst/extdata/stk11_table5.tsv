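variant	revel	colocated	pop_code	pop_points	func_points	comp_code	comp_points	pm5_points	total	category
p.G56W	0.932	NA	PM2	1	2	PP3	4	0	7	LP
p.P179R	0.939	P179Q|LP|0.94	PM2	1	2	PP3	4	1	8	LP
p.S193Y	0.871	NA	PM2	1	2	PP3	2	0	5	VUS-high
p.S216F	0.954	NA	PM2	1	2	PP3	4	0	7	LP
p.P221R	0.892	NA	PM2	1	2	PP3	2	0	5	VUS-high
p.F148S	0.728	NA	PM2	1	2	PP3	1	0	4	VUS-high
p.A241P	0.782	NA	PM2	1	2	PP3	2	0	5	VUS-high
p.R297M	0.936	R297S|P|0.94	PM2	1	2	PP3	4	2	9	LP
p.H202R	0.424	NA	NA	0	0	NA	0	0	0	VUS-low
p.W308R	0.881	W308C|LP|0.73;W308L|LP|0.84	PM2	1	2	PP3	2	2	7	LP
p.G242V	0.97	G242R|P|0.97	PM2	1	2	PP3	4	2	9	LP
p.G251C	0.833	NA	PM2	1	2	PP3	2	0	5	VUS-high
p.S31F	0.8	NA	PM2	1	-2	PP3	2	0	1	VUS-low
p.P275L	0.663	NA	PM2	1	-2	PP3	1	0	0	VUS-low
p.K84del	NA	NA	NA	0	-2	NA	0	0	-2	LB
p.R211Q	0.215	NA	NA	0	-2	BP4	-1	0	-3	LB
p.Q112E	0.393	NA	NA	0	-2	NA	0	0	-2	LB
p.G155R	0.382	NA	NA	0	-2	NA	0	0	-2	LB
p.R104G	0.582	NA	NA	0	-2	NA	0	0	-2	LB
p.R409W	0.238	NA	NA	0	-2	BP4	-1	0	-3	LB
p.A417S	0.102	NA	NA	0	-2	BP4	-2	0	-4	LB
p.A397S	0.03	NA	NA	0	-2	BP4	-2	0	-4	LB
p.P280A	0.097	NA	PM2	1	-2	BP4	-2	0	-3	LB
p.K311N	0.461	NA	PM2	1	-2	NA	0	0	-1	LB
p.D194Y	0.929	D194H|P|0.94;D194V|P|0.94;D194E|P|0.84	PM2	1	2	PP3	2	4	9	LP
p.G163R	0.933	G163D|P|0.95	PM2	1	2	PP3	4	0	7	LP
p.R297S	0.936	NA	PM2	1	2	PP3	4	0	7	LP
p.F354L	0.156	NA	BS1	-4	-2	BP4	-2	0	-8	B
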