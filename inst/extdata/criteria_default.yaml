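# Default three-level criteria hierarchy for prioritizing high-impact health
# technologies in a regional health service. Five domains, fifteen criteria,
# fifteen subcriteria. Nodes whose label carries "(placeholder)" stand in for
# items whose exact wording and placement in the published framework table is
# not available; replace them with your own configuration as needed. The
# configuration is data, not code.
name: high-impact-technology-mcda
version: "1.0"
domains:
  - id: d1
    label: Need for intervention
    description: >
      How pressing the health problem addressed by the technology is:
      the size of the affected population, the severity of the disease,
      and the extent of needs left unmet by current care.
    criteria:
      - id: d1.c1
        label: Affected population
        description: Size of the population affected by the target condition.
        subcriteria:
          - id: d1.c1.s1
            label: Disease prevalence (placeholder)
            description: Number of people living with the condition.
          - id: d1.c1.s2
            label: Disease incidence (placeholder)
            description: Rate of new cases of the condition.
      - id: d1.c2
        label: Disease severity
        description: Clinical seriousness of the condition if untreated.
        subcriteria:
          - id: d1.c2.s1
            label: Mortality burden (placeholder)
            description: Premature mortality attributable to the condition.
          - id: d1.c2.s2
            label: Morbidity burden (placeholder)
            description: Disability and suffering attributable to the condition.
      - id: d1.c3
        label: Unmet needs
        description: Needs of patients not covered by currently available care.
        subcriteria:
          - id: d1.c3.s1
            label: Unmet needs in HRQoL
            description: >
              Shortfall in health-related quality of life under current care.
          - id: d1.c3.s2
            label: Unmet needs in convenience
            description: >
              Burden of current care processes on patients and carers.
  - id: d2
    label: Outcomes of the intervention
    description: >
      What the technology delivers for patients relative to its comparators:
      effectiveness, safety, patient-perceived outcomes, and the type of
      benefit it provides.
    criteria:
      - id: d2.c1
        label: Comparative effectiveness
        description: Incremental health outcomes versus the relevant comparator.
        subcriteria:
          - id: d2.c1.s1
            label: Change in intermediate outcomes
            description: Effect on clinical or surrogate endpoints.
          - id: d2.c1.s2
            label: Change in HRQoL
            description: Effect on health-related quality of life.
      - id: d2.c2
        label: Comparative safety
        description: Incremental harms and risks versus the comparator.
        subcriteria:
          - id: d2.c2.s1
            label: Reduction in adverse events (placeholder)
            description: Change in frequency or seriousness of adverse events.
          - id: d2.c2.s2
            label: Tolerability (placeholder)
            description: Patient tolerability of the intervention.
      - id: d2.c3
        label: Patient-perceived outcomes
        description: Outcomes reported or perceived directly by patients.
        subcriteria:
          - id: d2.c3.s1
            label: Change in convenience
            description: Effect on convenience of care for patients and carers.
      - id: d2.c4
        label: Type of benefit
        description: >
          Nature of the benefit the technology provides; relocated into this
          domain from a stand-alone position during criteria selection.
        subcriteria:
          - id: d2.c4.s1
            label: Preventive benefit
            description: Benefit through prevention of disease or progression.
          - id: d2.c4.s2
            label: Therapeutic outcome
            description: Benefit through treatment of established disease.
  - id: d3
    label: Knowledge of the intervention
    description: >
      Quality and maturity of the evidence base and professional consensus
      supporting the technology.
    criteria:
      - id: d3.c1
        label: Quality of the evidence
        description: Internal and external validity of the supporting studies.
      - id: d3.c2
        label: Expert consensus
        description: Degree of agreement among clinical experts on its use.
      - id: d3.c3
        label: Completeness of reporting (placeholder)
        description: Extent and transparency of the available information.
  - id: d4
    label: Economic impact
    description: >
      Consequences of adoption for healthcare and non-healthcare budgets,
      including what must be displaced to fund it.
    criteria:
      - id: d4.c1
        label: Comparative cost consequences (placeholder)
        description: Incremental healthcare costs versus the comparator.
      - id: d4.c2
        label: Non-medical costs
        description: Costs falling outside the healthcare system.
      - id: d4.c3
        label: Opportunity costs and budget impact
        description: >
          Scale of the budget commitment and the value of services displaced.
        subcriteria:
          - id: d4.c3.s1
            label: Opportunity costs (placeholder)
            description: Value of the best alternative use of the resources.
          - id: d4.c3.s2
            label: Budget impact (placeholder)
            description: Net effect on the payer budget over the planning horizon.
  - id: d5
    label: Feasibility
    description: >
      Capacity of the health system to adopt the technology and the
      organizational consequences of doing so; added during criteria
      selection at the stakeholders' request.
    criteria:
      - id: d5.c1
        label: Organizational feasibility (placeholder)
        description: Fit with existing care pathways, staffing, and training.
      - id: d5.c2
        label: System capacity and resources (placeholder)
        description: Availability of infrastructure required for adoption.
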