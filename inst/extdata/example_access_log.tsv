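PT_MRN_ID	UA_TIME	MYC_UA_TYPE_C	UA_EXTENDED_INFO	UA_USER_AGENT	UA_SESSION_NUM
xxxxx	2018-09-17 09:20:38	Messaging	Medadvice-form	Null	56xxxx
xxxxx	2018-09-19 12:40:38	Messaging	Medadvice-form	Null	56xxxx
xxxxx	2018-09-19 12:53:12	Messaging	Medadvice-form	Null	56xxxx
xxxxx	2018-09-19 13:47:04	Login	Null	EpicMyChart-iPhone	56xxxx
xxxxx	2018-09-19 13:47:08	Provider List Widget	Get-prov-list	Null	56xxxx
xxxxx	2018-09-19 13:48:05	Messaging	Inbox message list	Null	56xxxx
xxxxx	2018-09-19 13:48:08	Messaging	Message read	Null	56xxxx
xxxxx	2018-09-19 13:48:37	Messaging	Inbox message list	Null	56xxxx
xxxxx	2018-09-19 13:49:05	Messaging	Message read	Null	56xxxx
xxxxx	2018-09-19 13:49:19	Messaging	Message read	Null	56xxxx
xxxxx	2018-09-19 13:50:07	Visits	Get future appt list	Null	56xxxx
xxxxx	2018-09-19 13:50:08	Visits	Get past appt list	Null	56xxxx
xxxxx	2018-09-19 13:50:19	Encounter Details	Past appt dat: 5xxx	Null	56xxxx
xxxxx	2018-09-19 14:06:00	Logout	Logout	Null	56xxxx
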