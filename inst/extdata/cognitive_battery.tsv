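test	domain
MMSE	global
MOCA	global
DKEFS_Stroop_Inhibition_Switching	executive
DKEFS_Verbal_Fluency_Category_Switching	executive
DKEFS_Trail_Number_Letter_Sequence	executive
WMS3_Letter_Number_Sequencing	working_memory
WMS3_Spatial_Span_Backward	working_memory
WAIS4_Digit_Span_Backward	working_memory
WAIS4_Digit_Span_Sequencing	working_memory
Rey_Complex_Figure_Immediate_Recall	episodic_memory
Rey_Complex_Figure_Delay_Recall	episodic_memory
WMS3_Verbal_Paired_Associates_I	episodic_memory
WMS3_Verbal_Paired_Associates_II	episodic_memory
WMS3_Logical_Memory_I	episodic_memory
WMS3_Logical_Memory_II	episodic_memory
Boston_Naming_Test	language
WAIS4_Symbol_Search	attention_speed
WAIS4_Code	attention_speed
DKEFS_Trail_Visual_Scanning	attention_speed
DKEFS_Trail_Number_Sequence	attention_speed
DKEFS_Trail_Letter_Sequence	attention_speed
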