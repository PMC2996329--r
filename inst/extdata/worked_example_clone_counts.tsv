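strain	condition	n_scored	n_hygS	class_I	class_II	class_III	class_other
MH3359	induced	1167	1062	910	141	11	0
MH3359	uninduced	1000	0	0	0	0	0
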