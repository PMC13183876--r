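name	role	group_class	requires_carbon	pattern
carboxylic_acid	acidic	carboxylic_acid	FALSE	[O;D1;H1,-:1]-[C]=[O;D1]
oxyacid_oh	acidic	oxyacid	FALSE	[O;D1;H1,-:1]-[S,P]=[O;D1]
phenol	acidic	phenol	FALSE	[O;D1;H1,-:1]-[c]
thiol	acidic	thiol	FALSE	[S;D1;H1,-:1]-[C,c]
sulfonamide_nh	acidic	sulfonamide	FALSE	[N;H1,H2,-:1]-[S](=[O;D1])=[O;D1]
imide_nh	acidic	imide	FALSE	[N;H1,-:1](-[C]=[O;D1])-[C]=[O;D1]
azole_nh	acidic	azole	FALSE	[n;H1&+0,-:1]
activated_ch	acidic	activated_carbon	TRUE	[C;H1,H2,H3:1](-[C]=[O;D1])-[C]=[O;D1]
amidine_n	basic	amidine	FALSE	[N;A;+0,+1;!$([N]-[C]=[O]):1]=[C]-[N]
imine_n	basic	imine	FALSE	[N;A;+0,+1;!$([N]-[C]=[O]):1]=[C]
aliphatic_amine	basic	amine	FALSE	[N;A;+0,+1;!$([N]~[C]=[O;D1]);!$([N]~[S]=[O;D1]);!$([N]-[C]=[N]);!$([N]=*);!$([N]#*):1]
pyridine_n	basic	pyridine	FALSE	[n;D2;H0&+0,H1&+1:1]
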