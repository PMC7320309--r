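# Default two-level action taxonomy: portal function -> action label ->
# matchers against the raw audit-log vocabulary.
#
# A label with no matchers matches its own display string (trimmed,
# case-insensitive) in MYC_UA_TYPE_C. Matchers with an `extended` key
# refine the match on UA_EXTENDED_INFO; `substring: true` matches the
# pattern as a substring. The raw-string matchers below cover the audit
# vocabulary observed in log excerpts; the raw MYC_UA_TYPE_C vocabulary is
# version- and site-dependent, so THIS SECTION IS SITE-EDITABLE — treat it
# as a starting point, not ground truth.

misc:
  login: ["Login"]
  logout: ["Logout"]
  two_factor: ["2-Factor Authentication", "Two-Factor Authentication"]

functions:
  Messaging:
    Letters:
    Message center:
      - { action: "Message center" }
      - { action: "Messaging", extended: "Inbox message list" }
      - { action: "Messaging", extended: "Message read" }
    Send new message:
      - { action: "Send new message" }
      - { action: "Messaging", extended: "Medadvice-form" }
  Visits:
    Appointment details:
      - { action: "Appointment details" }
      - { action: "Encounter Details" }
      - { action: "Visits" }
    Cancel an appointment:
    Driving directions:
    eCheck-in:
    Schedule an appointment:
      - { action: "Schedule an appointment" }
      - { action: "Provider List Widget" }
    Telemedicine:
    Upcoming tests:
  My record:
    Allergies:
    Current health issues:
    Flowsheet:
    Health summary:
    Immunizations:
    Medications:
    My conditions:
    Preventive care:
    Test results:
  Medical tools:
    Consolidate EMR:
    Download my record:
    Research studies:
    Share my record:
    Wallet card:
    Who accessed my record:
  Billing:
    Bill payment:
    Billing account details:
    Billing account summary:
    Change paperless status:
    Estimates:
    Insurance summary:
    Update insurance:
  Resources:
    Patient education:
    Terms and conditions:
  Proxy:
    Proxy forms:
    Proxy renewal request:
    Request child proxy access:
    Request proxy access:
    Switch proxy context:
  Preferences:
    About me:
    Manage my accounts:
    Notifications:
    Personalize:
    Security settings:
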